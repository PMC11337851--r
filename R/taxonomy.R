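# Taxonomic label canonicalization and abundance-threshold aggregation.
#
# Raw annotation labels (including synonyms and case/whitespace variants)
# are resolved against a local reference table of ranked lineages, then
# low-abundance taxa are merged upward: each input row is reported at the
# deepest rank of its lineage whose whole subtree reaches the minimum
# relative-abundance resolution T in at least one sample (default rule).
# A virtual "Root" sits above the top rank and absorbs anything whose
# lineage never reaches T; unknown labels can be bucketed under a reserved
# "Unclassified" child of Root.

ROOT_LABEL <- "Root"
UNCLASSIFIED_LABEL <- "Unclassified"

.norm_label <- function(x) tolower(trimws(x))

#' Build a taxonomy reference from a label table
#'
#' @param df data frame with columns `label` (raw label or synonym),
#'   `canonical` (canonical name), `rank` (e.g. domain...genus) and
#'   `parent` (canonical name of the parent; empty or `NA` for top-rank
#'   entries, which hang off a virtual root). Several labels may map to the
#'   same canonical entry (synonyms); a label mapping to different
#'   canonical entries is a homonym, resolved at lookup time.
#' @return an object of class `taxonomy_ref` holding the node table, the
#'   synonym index and the rank order (root-most first) inferred from
#'   parent depths.
#' @export
taxonomy_ref <- function(df) {
  need <- c("label", "canonical", "rank", "parent")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("taxonomy reference missing column(s): ", paste(miss, collapse = ", "))
  df$parent[is.na(df$parent)] <- ""
  nodes <- unique(df[, c("canonical", "rank", "parent")])
  if (anyDuplicated(nodes$canonical)) {
    bad <- nodes$canonical[duplicated(nodes$canonical)]
    stop("canonical entry with conflicting rank/parent: ",
         paste(unique(bad), collapse = ", "))
  }
  rownames(nodes) <- nodes$canonical
  orphan <- nodes$parent != "" & !(nodes$parent %in% nodes$canonical)
  if (any(orphan))
    stop("parent not in reference: ",
         paste(unique(nodes$parent[orphan]), collapse = ", "))

  # depth by walking parents; doubles as cycle detection
  depth <- stats::setNames(rep(NA_integer_, nrow(nodes)), nodes$canonical)
  for (cn in nodes$canonical) {
    d <- 0L; cur <- cn; seen <- character(0)
    while (cur != "") {
      if (cur %in% seen)
        stop("cycle in taxonomy reference at '", cur, "'")
      seen <- c(seen, cur)
      cur <- nodes[cur, "parent"]
      d <- d + 1L
      if (d > nrow(nodes)) stop("cycle in taxonomy reference")
    }
    depth[cn] <- d
  }
  rank_depth <- tapply(depth, nodes$rank, stats::median)
  ranks <- names(sort(rank_depth))

  syn <- split(df$canonical, .norm_label(df$label))
  syn <- lapply(syn, unique)
  # canonical names always resolve to themselves (needed for idempotent
  # re-merging of already-aggregated tables)
  for (cn in nodes$canonical) {
    k <- .norm_label(cn)
    if (is.null(syn[[k]])) syn[[k]] <- cn
  }

  structure(list(nodes = nodes, synonyms = syn, ranks = ranks,
                 depth = depth),
            class = "taxonomy_ref")
}

#' Read a taxonomy reference TSV
#'
#' Canonical on-disk form: columns label, canonical, rank, parent.
#' @param path TSV file.
#' @return `taxonomy_ref` object.
#' @export
read_taxonomy_ref <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  taxonomy_ref(df)
}

#' @export
print.taxonomy_ref <- function(x, ...) {
  cat("taxonomy_ref:", nrow(x$nodes), "canonical entries,",
      length(x$synonyms), "labels, ranks:",
      paste(x$ranks, collapse = " > "), "\n")
  invisible(x)
}

.lineage_of <- function(ref, canonical) {
  path <- character(0)
  cur <- canonical
  while (cur != "") {
    path <- c(cur, path)
    cur <- ref$nodes[cur, "parent"]
  }
  c(ROOT_LABEL, path)
}

#' Resolve a raw label to its ranked lineage
#'
#' Matching is case-insensitive and ignores surrounding whitespace;
#' synonyms resolve to the same canonical path. Homonyms (one label, two
#' canonical entries) prefer the entry under `context_domain` when given.
#'
#' @param label raw label string.
#' @param ref `taxonomy_ref`.
#' @param unknown_policy `"error"` rejects unknown labels; `"bucket"`
#'   assigns them to a reserved Unclassified child of the root.
#' @param context_domain optional top-rank name used to disambiguate
#'   homonyms (e.g. the majority domain of the table being merged).
#' @return character vector, the lineage from the virtual root down to the
#'   canonical entry (inclusive).
#' @export
canonicalize_label <- function(label, ref,
                               unknown_policy = c("error", "bucket"),
                               context_domain = NULL) {
  unknown_policy <- match.arg(unknown_policy)
  stopifnot(inherits(ref, "taxonomy_ref"))
  if (.norm_label(label) == .norm_label(ROOT_LABEL)) return(ROOT_LABEL)
  if (.norm_label(label) == .norm_label(UNCLASSIFIED_LABEL))
    return(c(ROOT_LABEL, UNCLASSIFIED_LABEL))
  hits <- ref$synonyms[[.norm_label(label)]]
  if (length(hits) > 1 && !is.null(context_domain)) {
    doms <- vapply(hits, function(h) .lineage_of(ref, h)[2], character(1))
    hits <- if (any(doms == context_domain)) hits[doms == context_domain] else hits
  }
  if (length(hits) != 1) {
    if (unknown_policy == "bucket")
      return(c(ROOT_LABEL, UNCLASSIFIED_LABEL))
    if (is.null(hits))
      stop("label not in taxonomy reference: '", label, "'")
    stop("ambiguous label '", label, "' (matches: ",
         paste(hits, collapse = ", "), ")")
  }
  .lineage_of(ref, hits)
}

.rank_of_node <- function(ref, node) {
  if (node == ROOT_LABEL) return("root")
  if (node == UNCLASSIFIED_LABEL) return("unclassified")
  ref$nodes[node, "rank"]
}

# Lineages for every row of a table, resolving homonyms against the
# majority domain (by total counts) of the unambiguous labels.
.table_lineages <- function(x, ref, unknown_policy) {
  labs <- rownames(x)
  first <- lapply(labs, function(l)
    tryCatch(canonicalize_label(l, ref, unknown_policy = "bucket"),
             error = function(e) NULL))
  dom <- vapply(first, function(p)
    if (!is.null(p) && length(p) >= 2) p[2] else NA_character_, character(1))
  w <- tapply(rowSums(x), dom, sum)
  w <- w[names(w) != UNCLASSIFIED_LABEL]
  majority <- if (length(w)) names(which.max(w)) else NULL
  lapply(labs, canonicalize_label, ref = ref,
         unknown_policy = unknown_policy, context_domain = majority)
}

#' Merge low-abundance taxa up their lineages to a minimum resolution
#'
#' Implements the threshold aggregation step: every input row is reported
#' at the deepest rank of its canonical lineage whose subtree (the row
#' itself plus all other rows descending from that rank) reaches the
#' relative-abundance threshold `threshold` under the retention rule.
#' Under the default `any_sample` rule the subtree must reach the threshold
#' in at least one sample and a single mapping is applied to every sample,
#' so all samples share one label set; under `per_sample` each sample is
#' aggregated by its own mapping. Rows whose lineage never reaches the
#' threshold fall into the virtual root bucket.
#'
#' Per-sample totals are conserved exactly (integer arithmetic when the
#' input is integer) and the operation is idempotent.
#'
#' @param x count table matrix (raw counts; relative abundances are
#'   computed internally for the retention test).
#' @param ref `taxonomy_ref`.
#' @param threshold minimum relative-abundance resolution in (0, 1);
#'   default 0.04.
#' @param retention_rule `"any_sample"` (default) or `"per_sample"`.
#' @param unknown_policy passed to [canonicalize_label()].
#' @return list with `table` (merged count matrix, labels in first-
#'   appearance order) and `report` (list: `mapping` data frame raw ->
#'   final label with final rank, `merged_mass` mean per-sample relative
#'   abundance carried by each final label, `rounds` the largest number of
#'   rank promotions applied to any row).
#' @export
merge_to_threshold <- function(x, ref, threshold = 0.04,
                               retention_rule = c("any_sample", "per_sample"),
                               unknown_policy = c("bucket", "error")) {
  retention_rule <- match.arg(retention_rule)
  unknown_policy <- match.arg(unknown_policy)
  validate_count_table(x)
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must lie strictly between 0 and 1")

  lins <- .table_lineages(x, ref, unknown_policy)
  rel <- relative_abundance(x)
  nodes <- unique(unlist(lins))

  # membership: node x row indicator (row descends from node, inclusively)
  memb <- matrix(0, length(nodes), nrow(x),
                 dimnames = list(nodes, rownames(x)))
  for (i in seq_len(nrow(x))) memb[lins[[i]], i] <- 1
  node_ab <- memb %*% rel  # subtree relative abundance per node x sample

  tol <- 1e-12
  pick_final <- function(lineage, keep) {
    hit <- lineage[lineage %in% nodes[keep]]
    if (length(hit)) hit[length(hit)] else ROOT_LABEL
  }

  if (retention_rule == "any_sample") {
    keep <- apply(node_ab, 1, max) >= threshold - tol
    keep[nodes == ROOT_LABEL] <- TRUE
    finals <- vapply(lins, pick_final, character(1), keep = keep)
    out_labels <- unique(finals)
    out <- rowsum(x, group = factor(finals, levels = out_labels))
    out <- out[out_labels, , drop = FALSE]
    mapping <- data.frame(raw_label = rownames(x), final_label = finals,
                          final_rank = vapply(finals, .rank_of_node,
                                              character(1), ref = ref),
                          stringsAsFactors = FALSE)
    promoted <- mapply(function(l, f) length(l) - match(f, l), lins, finals)
  } else {
    finals_s <- vapply(seq_len(ncol(x)), function(s) {
      keep <- node_ab[, s] >= threshold - tol
      keep[nodes == ROOT_LABEL] <- TRUE
      vapply(lins, pick_final, character(1), keep = keep)
    }, character(nrow(x)))
    if (nrow(x) == 1) finals_s <- matrix(finals_s, nrow = 1)
    out_labels <- unique(as.vector(finals_s))
    out <- matrix(0, length(out_labels), ncol(x),
                  dimnames = list(out_labels, colnames(x)))
    for (s in seq_len(ncol(x))) {
      rs <- tapply(x[, s], factor(finals_s[, s], levels = out_labels), sum)
      rs[is.na(rs)] <- 0
      out[, s] <- rs
    }
    mapping <- data.frame(raw_label = rep(rownames(x), ncol(x)),
                          sample_id = rep(colnames(x), each = nrow(x)),
                          final_label = as.vector(finals_s),
                          stringsAsFactors = FALSE)
    mapping$final_rank <- vapply(mapping$final_label, .rank_of_node,
                                 character(1), ref = ref)
    promoted <- mapply(function(l, f) length(l) - match(f, l),
                       lins, finals_s[, 1])
  }

  rel_out <- sweep(out, 2, colSums(x), "/")
  merged_mass <- rowMeans(rel_out)
  list(table = out,
       report = list(mapping = mapping,
                     merged_mass = merged_mass,
                     rounds = max(0L, as.integer(promoted))))
}
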