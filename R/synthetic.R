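#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions a generated cohort emulates. Disease and
#' neutral indels differ through a latent risk score `z` (disease
#' `z ~ N(1.2, 0.6)`, neutral `z ~ N(-1.2, 0.6)`): sites with high `z`
#' have low disorder, low (buried) ASA, high nucleotide conservation,
#' deep residue alignments (high n_eff), sharper profile emissions and
#' fewer gap transitions — the direction reported for disease-associated
#' NFS-indels. Neutral minor allele frequencies mix an independent
#' uniform draw with a monotone-decreasing transform of `z` at weight
#' `maf_coupling`, producing the negative MAF-risk trend.
#'
#' @param n_disease,n_neutral Class counts.
#' @param n_proteins Number of host proteins.
#' @param protein_len Length-2 integer range of protein lengths (residues).
#' @param indel_len_weights Probabilities of indel residue lengths 1, 2,
#'   3, ... (short-biased: most micro-indels span one or two residues).
#' @param ins_fraction Fraction of indels that are insertions.
#' @param maf_coupling Weight in \[0, 1\] of the risk-dependent MAF
#'   component for neutral records.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `nfs_cohort_config`.
#' @export
cohort_config <- function(n_disease = 100, n_neutral = 100, n_proteins = 40,
                          protein_len = c(80, 200),
                          indel_len_weights = c(0.6, 0.3, 0.1),
                          ins_fraction = 0.3, maf_coupling = 0.6,
                          seed = 1) {
  stopifnot(n_disease > 0, n_neutral > 0, n_proteins > 0,
            length(protein_len) == 2, protein_len[1] >= 40,
            all(indel_len_weights >= 0), sum(indel_len_weights) > 0,
            ins_fraction >= 0, ins_fraction <= 1,
            maf_coupling >= 0, maf_coupling <= 1)
  structure(list(
    n_disease = n_disease, n_neutral = n_neutral, n_proteins = n_proteins,
    protein_len = protein_len,
    indel_len_weights = indel_len_weights / sum(indel_len_weights),
    ins_fraction = ins_fraction, maf_coupling = maf_coupling,
    risk = list(disease = c(mean = 1.2, sd = 0.6),
                neutral = c(mean = -1.2, sd = 0.6)),
    seed = seed), class = "nfs_cohort_config")
}

CODON_OF <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# site-conditional track draws given latent risk z (z = 0 is background)
draw_site <- function(z, n) {
  mean_dis <- stats::plogis(-z)
  list(
    disorder = stats::rbeta(n, mean_dis * 8, (1 - mean_dis) * 8),
    asa = pmax(0, stats::rnorm(n, 50 - 15 * z, 15)),
    cons = stats::rnorm(n, 0.5 + 1.2 * z, 0.8),
    neff_m = pmax(0.5, stats::rnorm(n, 7 + 2 * z, 1.5)),
    gap_rate = pmin(0.4, pmax(0.005, 0.02 + 0.1 * stats::plogis(-z) +
                                stats::rnorm(n, 0, 0.01))),
    sharp = 2 * exp(0.8 * z)
  )
}

build_protein <- function(pid, len, strand) {
  q <- blosum62_background()
  aa <- sample(AA_ALPHABET, len, replace = TRUE, prob = q)
  seq_aa <- paste(aa, collapse = "")
  cds_tx <- paste0(paste(CODON_OF[aa], collapse = ""), "TAA")
  n_cds <- nchar(cds_tx)
  # split the CDS into two exons at a codon-interior-free point
  n1 <- 3 * floor(len / 2)
  intron_len <- 50L
  flank <- 30L
  if (strand == "+") {
    ex1 <- c(flank + 1L, flank + n1)
    ex2 <- c(flank + n1 + intron_len + 1L, flank + n_cds + intron_len)
    genome <- paste0(
      paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
            collapse = ""),
      substr(cds_tx, 1, n1),
      paste(sample(c("A", "C", "G", "T"), intron_len, replace = TRUE),
            collapse = ""),
      substr(cds_tx, n1 + 1, n_cds),
      paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
            collapse = ""))
  } else {
    # transcript reads right-to-left: 5' exon is the genomic-right one
    n2 <- n_cds - n1
    ex1 <- c(flank + 1L, flank + n2)                      # genomic left
    ex2 <- c(flank + n2 + intron_len + 1L, flank + n_cds + intron_len)
    genome <- paste0(
      paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
            collapse = ""),
      revcomp(substr(cds_tx, n1 + 1, n_cds)),
      paste(sample(c("A", "C", "G", "T"), intron_len, replace = TRUE),
            collapse = ""),
      revcomp(substr(cds_tx, 1, n1)),
      paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
            collapse = ""))
  }
  ivals <- tibble::tibble(start = as.integer(c(ex1[1], ex2[1])),
                          end = as.integer(c(ex1[2], ex2[2])))
  tibble::tibble(
    transcript_id = paste0("tx_", pid), chrom = paste0("chr_", pid),
    strand = strand, protein_id = pid, protein_seq = seq_aa,
    protein_len = len, exons = list(ivals), cds = list(ivals),
    cds_seq = cds_tx, genome_seq = genome)
}

# background (z = 0) residue track and profile for one protein
build_background_tracks <- function(tx) {
  len <- tx$protein_len
  site <- draw_site(0, len)
  ss_state <- sample(c("C", "H", "E"), len, replace = TRUE,
                     prob = c(0.45, 0.35, 0.2))
  pss <- t(vapply(ss_state, function(s) {
    p <- rdirichlet1(c(C = 1, H = 1, E = 1) + 6 * (c("C", "H", "E") == s))
    p
  }, c(C = 0, H = 0, E = 0)))
  residue <- tibble::tibble(
    pos = seq_len(len), residue = strsplit(tx$protein_seq, "")[[1]],
    disorder = site$disorder, asa = site$asa,
    pC = pss[, 1], pH = pss[, 2], pE = pss[, 3],
    ss = c("C", "H", "E")[max.col(pss, ties.method = "first")])
  q <- blosum62_background()
  aa <- strsplit(tx$protein_seq, "")[[1]]
  profile <- make_profile_rows(aa, site, q)
  cons <- stats::rnorm(nchar(tx$genome_seq), 0.5, 1)
  list(residue = residue, profile = profile, cons = cons)
}

make_profile_rows <- function(aa, site, q) {
  len <- length(aa)
  em <- t(vapply(seq_len(len), function(i) {
    alpha <- q * 5 + (AA_ALPHABET == aa[i]) * site$sharp[
      min(i, length(site$sharp))]
    rdirichlet1(alpha)
  }, numeric(20)))
  colnames(em) <- AA_ALPHABET
  g <- site$gap_rate
  if (length(g) == 1) g <- rep(g, len)
  t_mi <- g / 2; t_md <- g / 2
  t_mm <- 1 - t_mi - t_md
  t_im <- pmin(0.95, pmax(0.6, stats::rnorm(len, 0.8, 0.05)))
  t_dm <- pmin(0.95, pmax(0.6, stats::rnorm(len, 0.8, 0.05)))
  trans <- cbind(t_MM = t_mm, t_MI = t_mi, t_MD = t_md,
                 t_IM = t_im, t_II = 1 - t_im, t_DM = t_dm, t_DD = 1 - t_dm)
  nm <- site$neff_m
  if (length(nm) == 1) nm <- rep(nm, len)
  neff <- cbind(neff_M = nm, neff_I = nm * g, neff_D = nm * g)
  list(emissions = em, transitions = trans, neff = neff)
}

#' Generate a synthetic NFS-indel cohort
#'
#' Builds proteins, transcript models (two exons, both strands), genomes,
#' codon-aligned NFS insertions and deletions with class labels, and all
#' annotation tracks (per-base conservation, per-residue structure,
#' per-protein profiles), with disease sites drawn from
#' low-disorder/low-ASA/high-conservation distributions and neutral sites
#' the reverse. Fully reproducible from the config seed.
#'
#' @param cfg An [cohort_config()].
#' @return A list of class `nfs_cohort`: `indels` (VCF-style tibble with
#'   `transcript_id`), `transcripts`, `cons_track`, `residue_tracks`,
#'   `profiles` (both named by protein id), `truth` (per-indel latent risk
#'   and site parameters), `cfg`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "nfs_cohort_config"))
  set.seed(cfg$seed)
  lens <- sample(seq(cfg$protein_len[1], cfg$protein_len[2]),
                 cfg$n_proteins, replace = TRUE)
  strands <- rep_len(c("+", "+", "+", "-"), cfg$n_proteins)
  transcripts <- dplyr::bind_rows(purrr::map(seq_len(cfg$n_proteins),
    function(p) build_protein(paste0("prot_", p), lens[p], strands[p])))
  tracks <- purrr::map(seq_len(nrow(transcripts)),
                       function(i) build_background_tracks(transcripts[i, ]))
  names(tracks) <- transcripts$protein_id
  used <- purrr::map(lens, function(l) logical(l))  # residues already hosting
  names(used) <- transcripts$protein_id

  n <- cfg$n_disease + cfg$n_neutral
  labels <- c(rep("disease", cfg$n_disease), rep("neutral", cfg$n_neutral))
  indel_rows <- list(); truth_rows <- list()
  for (i in seq_len(n)) {
    lab <- labels[i]
    rp <- cfg$risk[[lab]]
    z <- stats::rnorm(1, rp["mean"], rp["sd"])
    k <- sample(seq_along(cfg$indel_len_weights), 1,
                prob = cfg$indel_len_weights)
    kind <- if (stats::runif(1) < cfg$ins_fraction) "insertion" else "deletion"
    placed <- FALSE
    span <- if (kind == "deletion") k else 2L
    for (ti in sample(nrow(transcripts))) {
      tx <- transcripts[ti, ]
      L <- tx$protein_len
      lo <- 10L; hi <- L - 9L - span
      if (hi < lo) next
      ind <- NULL
      for (r in sample(seq.int(lo, hi))) {
        site_res <- seq.int(r - 8L, r + span + 7L)     # window + margin
        if (any(used[[tx$protein_id]][site_res])) next
        ind <- make_indel_record(tx, r, k, kind, i)
        if (!is.null(ind)) break
      }
      if (is.null(ind)) next
      used[[tx$protein_id]][site_res] <- TRUE
      # overwrite tracks at the site with risk-conditional draws
      site <- draw_site(z, length(site_res))
      tracks[[tx$protein_id]] <- apply_site(tracks[[tx$protein_id]], tx,
                                            site_res, site,
                                            strsplit(tx$protein_seq,
                                                     "")[[1]][site_res])
      maf <- if (lab == "neutral") {
        (1 - cfg$maf_coupling) * stats::runif(1, 0, 0.5) +
          cfg$maf_coupling * 0.5 * stats::plogis(-2 * z)
      } else NA_real_
      indel_rows[[i]] <- dplyr::mutate(ind, label = lab, maf = maf)
      truth_rows[[i]] <- tibble::tibble(
        id = ind$id, label = lab, latent_risk = z, kind = kind,
        transcript_id = tx$transcript_id, protein_id = tx$protein_id,
        residue = r, n_res = k, maf = maf)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("Could not place indel ", i, "; proteins too short or too few ",
           "for the requested cohort size.", call. = FALSE)
    }
  }
  indels <- dplyr::bind_rows(indel_rows)
  cons_track <- dplyr::bind_rows(purrr::map(seq_len(nrow(transcripts)),
    function(j) {
      tibble::tibble(chrom = transcripts$chrom[j],
                     pos = seq_along(tracks[[j]]$cons),
                     score = tracks[[j]]$cons)
    }))
  class(cons_track) <- c("nfs_cons_track", class(tibble::tibble()))
  residue_tracks <- purrr::map(tracks, function(t) {
    structure(t$residue, asa_units = "abs",
              class = c("nfs_residue_track", class(tibble::tibble())))
  })
  profiles <- purrr::imap(tracks, function(t, pid) {
    structure(list(protein_id = pid, emissions = t$profile$emissions,
                   transitions = t$profile$transitions,
                   neff = t$profile$neff,
                   background = blosum62_background()),
              class = "nfs_profile")
  })
  structure(list(indels = indels, transcripts = transcripts,
                 cons_track = cons_track, residue_tracks = residue_tracks,
                 profiles = profiles,
                 truth = dplyr::bind_rows(truth_rows), cfg = cfg),
            class = "nfs_cohort")
}

# build the VCF-style record for a codon-aligned indel at residue r
make_indel_record <- function(tx, r, k, kind, i) {
  cdsp <- cds_positions(tx)
  genome <- strsplit(tx$genome_seq, "")[[1]]
  if (kind == "deletion") {
    idx <- seq.int(3 * (r - 1) + 1, 3 * (r + k - 1))
    gpos <- cdsp[idx]
    lo <- min(gpos); hi <- max(gpos)
    if (hi - lo + 1 != length(gpos)) return(NULL)  # crosses the intron
    anchor <- lo - 1L
    if (anchor < 1) return(NULL)
    ref <- paste(genome[anchor:hi], collapse = "")
    alt <- genome[anchor]
    pos <- anchor
  } else {
    c5 <- 3 * r               # insert between codon r and r+1
    g1 <- cdsp[c5]; g2 <- cdsp[c5 + 1]
    if (abs(g1 - g2) != 1) return(NULL)
    ins_aa <- sample(AA_ALPHABET, k, replace = TRUE)
    ins_tx <- paste(CODON_OF[ins_aa], collapse = "")
    ins_fwd <- if (tx$strand == "-") revcomp(ins_tx) else ins_tx
    pos <- min(g1, g2)
    ref <- genome[pos]
    alt <- paste0(ref, ins_fwd)
  }
  tibble::tibble(id = sprintf("indel_%04d", i), chrom = tx$chrom,
                 pos = as.integer(pos), ref = ref, alt = alt, kind = kind,
                 net_len = 3L * k, transcript_id = tx$transcript_id)
}

apply_site <- function(track, tx, site_res, site, aa_site) {
  track$residue$disorder[site_res] <- site$disorder
  track$residue$asa[site_res] <- site$asa
  prof <- make_profile_rows(aa_site, site, blosum62_background())
  track$profile$emissions[site_res, ] <- prof$emissions
  track$profile$transitions[site_res, ] <- prof$transitions
  track$profile$neff[site_res, ] <- prof$neff
  # conservation on the genomic bases of the site codons
  cdsp <- cds_positions(tx)
  idx <- seq.int(3 * (min(site_res) - 1) + 1,
                 min(3 * max(site_res), length(cdsp)))
  gpos <- cdsp[idx]
  track$cons[gpos] <- rep(site$cons, length.out = length(gpos))
  track
}

#' Write a synthetic cohort to disk in standard formats
#'
#' VCF (with `LABEL` and `AF` INFO keys), GTF + protein FASTA, bedGraph
#' conservation, one residue-track TSV and one profile TSV per protein,
#' and the truth table.
#'
#' @param cohort An `nfs_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tdir <- file.path(dir, "tracks")
  dir.create(tdir, showWarnings = FALSE)
  ind <- cohort$indels
  info <- paste0("LABEL=", ind$label,
                 ifelse(is.na(ind$maf), "",
                        paste0(";AF=", format(ind$maf, digits = 10))))
  vcf <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=LABEL,Number=1,Type=String,Description=\"Class label\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
           paste0("##contig=<ID=", unique(ind$chrom), ">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           paste(ind$chrom, ind$pos, ind$id, ind$ref, ind$alt, ".", "PASS",
                 info, sep = "\t"))
  writeLines(vcf, file.path(dir, "indels.vcf"))
  gtf <- purrr::map(seq_len(nrow(cohort$transcripts)), function(i) {
    tx <- cohort$transcripts[i, ]
    ex <- tx$exons[[1]]
    attrs <- paste0("transcript_id \"", tx$transcript_id,
                    "\"; protein_id \"", tx$protein_id, "\";")
    c(paste(tx$chrom, "synth", "exon", ex$start, ex$end, ".", tx$strand,
            ".", attrs, sep = "\t"),
      paste(tx$chrom, "synth", "CDS", ex$start, ex$end, ".", tx$strand,
            "0", attrs, sep = "\t"))
  })
  writeLines(unlist(gtf), file.path(dir, "transcripts.gtf"))
  aa <- Biostrings::AAStringSet(cohort$transcripts$protein_seq)
  names(aa) <- cohort$transcripts$protein_id
  Biostrings::writeXStringSet(aa, file.path(dir, "proteins.fasta"))
  ct <- cohort$cons_track
  writeLines(paste(ct$chrom, ct$pos - 1L, ct$pos,
                   format(ct$score, digits = 10, trim = TRUE), sep = "\t"),
             file.path(dir, "conservation.bedGraph"))
  for (pid in names(cohort$residue_tracks)) {
    rt <- cohort$residue_tracks[[pid]]
    lines <- c(paste0("#protein_id ", pid, " len ", nrow(rt),
                      " asa_units abs"),
               paste(rt$pos, rt$residue,
                     format(rt$disorder, digits = 10, trim = TRUE),
                     format(rt$asa, digits = 10, trim = TRUE),
                     format(rt$pC, digits = 10, trim = TRUE),
                     format(rt$pH, digits = 10, trim = TRUE),
                     format(rt$pE, digits = 10, trim = TRUE),
                     rt$ss, sep = "\t"))
    writeLines(lines, file.path(tdir, paste0(pid, "_residue.tsv")))
    pr <- cohort$profiles[[pid]]
    fmt <- function(m) apply(m, 1, function(r) {
      paste(format(r, digits = 12, trim = TRUE, scientific = FALSE),
            collapse = "\t")
    })
    lines <- c(paste0("#protein_id ", pid, " len ", nrow(pr$emissions)),
               paste0("#bg ", paste(format(pr$background, digits = 10,
                                           trim = TRUE), collapse = " ")),
               paste(seq_len(nrow(pr$emissions)), fmt(pr$emissions),
                     fmt(pr$transitions), fmt(pr$neff), sep = "\t"))
    writeLines(lines, file.path(tdir, paste0(pid, "_profile.tsv")))
  }
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Load a written cohort back through the standard readers
#'
#' Re-reads every file written by [write_cohort()] with the package's own
#' parsers, assigning each indel its transcript by chromosome (one
#' transcript per chromosome in generated cohorts).
#'
#' @param dir Cohort directory.
#' @return A list with `indels`, `transcripts`, `cons_track`,
#'   `residue_tracks`, `profiles`, `truth`.
#' @export
load_cohort <- function(dir) {
  indels <- read_vcf(file.path(dir, "indels.vcf"))
  transcripts <- read_transcripts(file.path(dir, "transcripts.gtf"),
                                  file.path(dir, "proteins.fasta"))
  indels$transcript_id <- transcripts$transcript_id[
    match(indels$chrom, transcripts$chrom)]
  tdir <- file.path(dir, "tracks")
  pids <- transcripts$protein_id
  residue_tracks <- stats::setNames(lapply(pids, function(p) {
    read_residue_track(file.path(tdir, paste0(p, "_residue.tsv")))
  }), pids)
  profiles <- stats::setNames(lapply(pids, function(p) {
    read_profile(file.path(tdir, paste0(p, "_profile.tsv")))
  }), pids)
  list(indels = indels, transcripts = transcripts,
       cons_track = read_conservation(file.path(dir,
                                                "conservation.bedGraph")),
       residue_tracks = residue_tracks, profiles = profiles,
       truth = readr::read_tsv(file.path(dir, "truth.tsv"),
                               show_col_types = FALSE))
}

#' Analytic AUC of a single Gaussian feature
#'
#' For a feature distributed `N(mu0, sd0)` in the neutral class and
#' `N(mu1, sd1)` in the disease class, the ROC area of the feature itself
#' is `pnorm(|mu1 - mu0| / sqrt(sd0^2 + sd1^2))` — the recovery target for
#' end-to-end classifier checks on synthetic cohorts.
#'
#' @param mu0,sd0 Neutral-class mean and standard deviation.
#' @param mu1,sd1 Disease-class mean and standard deviation.
#' @return Numeric AUC in \[0.5, 1\] (for `mu1 >= mu0`).
#' @export
analytic_auc <- function(mu0, sd0, mu1, sd1) {
  stopifnot(sd0 > 0, sd1 > 0)
  stats::pnorm(abs(mu1 - mu0) / sqrt(sd0^2 + sd1^2))
}

#' Simulate a feature-level cohort
#'
#' A lighter companion to [generate_cohort()]: draws one informative
#' Gaussian feature (class-conditional means/sds) plus pure-noise
#' features, with neutral MAFs negatively coupled to the informative
#' feature. Used to validate the classifier stack against analytic
#' targets at large n.
#'
#' @param n_disease,n_neutral Class counts.
#' @param mu0,sd0,mu1,sd1 Informative-feature parameters
#'   (neutral/disease); defaults give an analytic AUC of
#'   `pnorm(1.4142) ~ 0.92`.
#' @param n_noise Number of standard-normal noise features (`noise_1`...).
#' @param maf_coupling Weight of the risk-coupled MAF component for
#'   neutral records.
#' @param seed Integer seed.
#' @return Tibble with `id`, `label`, `f_info`, noise columns and `maf`.
#' @export
simulate_feature_cohort <- function(n_disease, n_neutral, mu0 = 0, sd0 = 1,
                                    mu1 = 2, sd1 = 1, n_noise = 0,
                                    maf_coupling = 0.6, seed = 1) {
  set.seed(seed)
  n <- n_disease + n_neutral
  label <- c(rep("disease", n_disease), rep("neutral", n_neutral))
  f <- c(stats::rnorm(n_disease, mu1, sd1), stats::rnorm(n_neutral, mu0, sd0))
  z <- (f - (mu0 + mu1) / 2) / sqrt((sd0^2 + sd1^2) / 2)
  maf <- ifelse(label == "neutral",
                (1 - maf_coupling) * stats::runif(n, 0, 0.5) +
                  maf_coupling * 0.5 * stats::plogis(-2 * z),
                NA_real_)
  out <- tibble::tibble(id = sprintf("rec_%05d", seq_len(n)), label = label,
                        f_info = f, maf = maf)
  if (n_noise > 0) {
    noise <- matrix(stats::rnorm(n * n_noise), n, n_noise,
                    dimnames = list(NULL, paste0("noise_", seq_len(n_noise))))
    out <- dplyr::bind_cols(out, tibble::as_tibble(noise))
  }
  out
}

#' Build the small worked fixture cohort
#'
#' A deterministic miniature cohort (5 proteins, 14 indels, seed 42)
#' written to `dir`; its feature vectors and splice distances are frozen
#' in `inst/extdata/worked_fixture_truth.tsv` after oracle verification
#' and guarded by a regression test.
#'
#' @param dir Output directory (default: a fresh temporary directory).
#' @return The cohort directory path, with the in-memory cohort attached
#'   as attribute `cohort`.
#' @export
make_worked_fixture <- function(dir = tempfile("fixture")) {
  cfg <- cohort_config(n_disease = 7, n_neutral = 7, n_proteins = 5,
                       protein_len = c(80, 120), seed = 42)
  cohort <- generate_cohort(cfg)
  write_cohort(cohort, dir)
  structure(dir, cohort = cohort)
}
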