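#' Pairwise protein sequence identity
#'
#' Global alignment (BLOSUM62, gap open 11, gap extension 1) of two protein
#' sequences; identity is the percentage of identical columns over the
#' full alignment length.
#'
#' @param a,b Amino-acid strings.
#' @return Percent identity in \[0, 100\]; symmetric in its arguments.
#' @export
pairwise_identity <- function(a, b) {
  for (s in c(a, b)) {
    res <- strsplit(s, "")[[1]]
    if (length(res) == 0 || any(!res %in% AA_ALPHABET)) {
      stop("Sequences must be non-empty over the 20-letter amino-acid ",
           "alphabet.", call. = FALSE)
    }
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  su <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(pa == su) / length(pa)
}

#' Cluster proteins by sequence identity
#'
#' Single-linkage connected components of the graph whose edges join
#' protein pairs with identity above the threshold — the redundancy
#' reduction applied before training so no two training proteins are
#' recognisable homologues. The representative of a cluster is its longest
#' member (ties broken by lexicographic id).
#'
#' @param seqs Named character vector of protein sequences (names are
#'   unique protein ids).
#' @param threshold Identity threshold in percent; pairs strictly above it
#'   are linked. Default 35.
#' @return A tibble with columns `cluster`, `representative`, `protein_id`;
#'   clusters partition the input.
#' @export
cluster_at_identity <- function(seqs, threshold = 35) {
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("`seqs` must be named with unique protein ids.", call. = FALSE)
  }
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        if (pairwise_identity(seqs[[i]], seqs[[j]]) > threshold) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  comp <- match(root, unique(root))
  purrr::map_dfr(seq_len(max(comp)), function(k) {
    members <- ids[comp == k]
    lens <- nchar(seqs[members])
    rep_id <- members[order(-lens, members)][1]
    tibble::tibble(cluster = k, representative = rep_id,
                   protein_id = members)
  })
}

#' Keep only records on cluster-representative proteins
#'
#' Drops indel records whose protein is a non-representative cluster
#' member, reporting how many were removed.
#'
#' @param clusters Tibble from [cluster_at_identity()].
#' @param records Tibble with a `protein_id` column.
#' @return Filtered `records`.
#' @export
select_representatives <- function(clusters, records) {
  orphan <- setdiff(unique(records$protein_id), clusters$protein_id)
  if (length(orphan) > 0) {
    stop("Record protein id(s) absent from clusters: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  reps <- unique(clusters$representative)
  kept <- records[records$protein_id %in% reps, ]
  message("select_representatives: removed ", nrow(records) - nrow(kept),
          " record(s) on non-representative proteins.")
  kept
}
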