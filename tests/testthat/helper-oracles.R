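# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force / closed form rather than calling the package's
# own implementation paths.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# --- profile alignment -------------------------------------------------

# random tiny profile with valid invariants
random_profile <- function(n_cols, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rdir <- function(alpha) {
    g <- rgamma(length(alpha), alpha)
    g / sum(g)
  }
  em <- t(replicate(n_cols, rdir(rep(0.8, 20))))
  colnames(em) <- AA20
  mrow <- t(replicate(n_cols, rdir(c(6, 1, 1))))
  im <- runif(n_cols, 0.5, 0.95)
  dm <- runif(n_cols, 0.5, 0.95)
  trans <- cbind(t_MM = mrow[, 1], t_MI = mrow[, 2], t_MD = mrow[, 3],
                 t_IM = im, t_II = 1 - im, t_DM = dm, t_DD = 1 - dm)
  neff <- cbind(neff_M = runif(n_cols, 1, 10), neff_I = runif(n_cols, 0, 2),
                neff_D = runif(n_cols, 0, 2))
  bg <- rdir(rep(4, 20))
  names(bg) <- AA20
  structure(list(protein_id = "toy", emissions = em, transitions = trans,
                 neff = neff, background = bg), class = "nfs_profile")
}

# exhaustive enumeration of all global alignment paths; must agree with the
# Viterbi implementation on small problems
brute_profile_score <- function(seq, prof) {
  res <- strsplit(seq, "")[[1]]
  idx <- match(res, AA20)
  n <- nrow(prof$emissions)
  m <- length(idx)
  lemit <- log2(prof$emissions[, idx, drop = FALSE] /
                  rep(prof$background[idx], each = n))
  begin <- c(t_MM = 1 / 3, t_MI = 1 / 3, t_MD = 1 / 3,
             t_IM = 1 / 2, t_II = 1 / 2, t_DM = 1 / 2, t_DD = 1 / 2)
  lt <- log2(rbind(begin, prof$transitions))  # row j+1 = out of column j
  best <- -Inf
  recurse <- function(type, j, i, score) {
    if (j == n && i == m) {
      best <<- max(best, score)
      # paths may still continue through inserts only if i < m, so stop here
    }
    out <- lt[j + 1, ]
    if (j < n && i < m) {  # match move
      tr <- switch(type, M = out["t_MM"], I = out["t_IM"], D = out["t_DM"])
      recurse("M", j + 1, i + 1, score + tr + lemit[j + 1, i + 1])
    }
    if (j < n && type != "I") {  # delete move
      tr <- switch(type, M = out["t_MD"], D = out["t_DD"])
      recurse("D", j + 1, i, score + tr)
    }
    if (i < m && type != "D") {  # insert move (stays at column j)
      tr <- switch(type, M = out["t_MI"], I = out["t_II"])
      recurse("I", j, i + 1, score + tr)
    }
  }
  recurse("M", 0, 0, 0)
  unname(best)
}

random_aa_seq <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

# --- metrics -----------------------------------------------------------

# phi coefficient computed as the Pearson correlation of the two binary
# indicator vectors reconstructed from a confusion table
phi_from_counts <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  suppressWarnings(cor(truth, pred))
}

# Mann-Whitney U normalisation of the AUC, with the standard 0.5 tie credit
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[labels == "disease"]
  neg <- scores[labels == "neutral"]
  u <- 0
  for (p in pos) u <- u + sum(p > neg) + 0.5 * sum(p == neg)
  u / (length(pos) * length(neg))
}

# --- toy transcripts ---------------------------------------------------

# deterministic codon-backed transcript via the generator's builder
toy_transcript <- function(len = 100, strand = "+", seed = 7) {
  set.seed(seed)
  nfsindel:::build_protein("toy_prot", len, strand)
}

# a deletion record removing CDS indices c1..c2 of a toy transcript
toy_deletion <- function(tx, c1, c2, id = "del1") {
  cdsp <- nfsindel:::cds_positions(tx)
  g <- strsplit(tx$genome_seq, "")[[1]]
  gpos <- cdsp[c1:c2]
  lo <- min(gpos); hi <- max(gpos)
  stopifnot(hi - lo + 1 == length(gpos))
  tibble::tibble(id = id, chrom = tx$chrom, pos = lo - 1L,
                 ref = paste(g[(lo - 1):hi], collapse = ""),
                 alt = g[lo - 1], kind = "deletion",
                 net_len = c2 - c1 + 1L, label = "unknown", maf = NA_real_,
                 transcript_id = tx$transcript_id)
}

# an insertion of `aa` residues between codons r and r+1
toy_insertion <- function(tx, r, aa = "G", id = "ins1") {
  cdsp <- nfsindel:::cds_positions(tx)
  g1 <- cdsp[3 * r]; g2 <- cdsp[3 * r + 1]
  stopifnot(abs(g1 - g2) == 1)
  g <- strsplit(tx$genome_seq, "")[[1]]
  ins_tx <- paste(nfsindel:::CODON_OF[strsplit(aa, "")[[1]]], collapse = "")
  ins_fwd <- if (tx$strand == "-") nfsindel:::revcomp(ins_tx) else ins_tx
  pos <- min(g1, g2)
  tibble::tibble(id = id, chrom = tx$chrom, pos = as.integer(pos),
                 ref = g[pos], alt = paste0(g[pos], ins_fwd),
                 kind = "insertion", net_len = 3L * nchar(aa),
                 label = "unknown", maf = NA_real_,
                 transcript_id = tx$transcript_id)
}

# brute-force splice distances: enumerate the host exon's bases in
# transcript orientation and count strictly-before / strictly-after bases
brute_splice <- function(tx, aff) {
  exons <- tx$exons[[1]]
  host <- which(min(aff) >= exons$start & max(aff) <= exons$end)
  stopifnot(length(host) == 1)
  bases <- seq.int(exons$start[host], exons$end[host])
  if (tx$strand == "-") bases <- rev(bases)
  i <- match(aff, bases)
  c(d5 = min(i) - 1L, d3 = length(bases) - max(i))
}
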