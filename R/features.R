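#' Canonical 58-feature inventory
#'
#' The frozen, ordered names of the indel feature vector: 5 nucleotide
#' sequence-level features (2 splice distances + min/ave/max DNA
#' conservation), 35 protein sequence-level features (min/ave/max of the 7
#' profile transition probabilities and 3 effective sequence numbers = 30;
#' protein length, indel length, distances to the two termini = 4; the
#' indel-induced change to the profile match score = 1), and 18 structure
#' features (min/ave/max disorder, 3x3 secondary-structure probabilities,
#' 3 state fractions, min/ave/max ASA). Serialized models reference
#' features by these names, so the order is part of the package's contract.
#'
#' @return Character vector of 58 names with a `group` attribute
#'   (`"nucleotide"`, `"protein"`, `"structure"`).
#' @export
feature_names <- function() {
  nuc <- c("d5", "d3", "cons_min", "cons_ave", "cons_max")
  evo <- as.vector(t(outer(c(TRANSITION_NAMES, NEFF_NAMES),
                           c("min", "ave", "max"), paste, sep = "_")))
  protein <- c(evo, "protein_len", "indel_len", "dN", "dC", "delta_s")
  structure <- c(paste("disorder", c("min", "ave", "max"), sep = "_"),
                 as.vector(t(outer(c("pC", "pH", "pE"),
                                   c("min", "ave", "max"), paste, sep = "_"))),
                 "fC", "fH", "fE",
                 paste("asa", c("min", "ave", "max"), sep = "_"))
  out <- c(nuc, protein, structure)
  attr(out, "group") <- rep(c("nucleotide", "protein", "structure"),
                            c(length(nuc), length(protein), length(structure)))
  out
}

# nucleotide window on the genome for one indel
nucleotide_window <- function(indel, n_window) {
  if (indel$kind == "deletion") {
    seq.int(indel$pos + 1L - n_window, indel$pos + indel$net_len + n_window)
  } else {
    seq.int(indel$pos - n_window, indel$pos + 1L + n_window)
  }
}

#' Nucleotide sequence-level features
#'
#' The distances from the indel to the nearest 5' and 3' splice boundaries
#' and the min/ave/max phyloP-style conservation score over the windowed
#' bases: the deleted bases plus `n_window` on each side for a deletion
#' (`n_del + 2 n_window` bases), or the two bases flanking the insertion
#' point plus `n_window` on each side (`2 + 2 n_window` bases).
#'
#' @param indel One-row indel tibble (from [read_vcf()]).
#' @param transcript One-row transcript tibble.
#' @param cons_track Conservation track from [read_conservation()].
#' @param n_window Half-window size, 0..7.
#' @return Named numeric vector `d5, d3, cons_min, cons_ave, cons_max`.
#' @export
nucleotide_features <- function(indel, transcript, cons_track, n_window) {
  d <- splice_distances_one(indel, transcript)
  win <- nucleotide_window(indel, n_window)
  agg <- aggregate_window(conservation_at(cons_track, indel$chrom, win))
  c(d5 = unname(d[1]), d3 = unname(d[2]),
    cons_min = unname(agg["min"]), cons_ave = unname(agg["ave"]),
    cons_max = unname(agg["max"]))
}

# residue-level window for a protein indel
residue_region <- function(pindel, n_window, len = pindel$protein_len) {
  if (pindel$kind == "deletion") {
    deletion_region(pindel$first_res, pindel$last_res, n_window, len)
  } else {
    insertion_region(pindel$first_res, n_window, len)
  }
}

#' Evolutionary (profile) features
#'
#' Min/ave/max over the residue window of each of the 7 position-dependent
#' transition probabilities (MM, MI, MD, IM, II, DM, DD) and the 3
#' effective numbers of homologous sequences, 30 features in canonical
#' order.
#'
#' @param pindel One-row protein-indel tibble (from [map_to_protein()]).
#' @param profile An `nfs_profile`.
#' @param n_window Half-window size.
#' @return Named numeric vector of 30 values.
#' @export
evolution_features <- function(pindel, profile, n_window) {
  if (nrow(profile$emissions) != pindel$protein_len) {
    stop("Profile for ", pindel$protein_id, " has ",
         nrow(profile$emissions), " columns but protein length is ",
         pindel$protein_len, ".", call. = FALSE)
  }
  region <- residue_region(pindel, n_window)
  cols <- cbind(profile$transitions, profile$neff)
  out <- unlist(lapply(colnames(cols), function(nm) {
    agg <- aggregate_window(cols[region, nm])
    stats::setNames(agg, paste(nm, c("min", "ave", "max"), sep = "_"))
  }))
  out
}

#' Length and terminal-distance features
#'
#' Protein length, indel length in residues, and the residue distances
#' from the indel to the amino and carboxyl termini.
#'
#' @inheritParams evolution_features
#' @return Named numeric vector `protein_len, indel_len, dN, dC`.
#' @export
length_features <- function(pindel) {
  c(protein_len = as.numeric(pindel$protein_len),
    indel_len = as.numeric(pindel$n_del),
    dN = as.numeric(pindel$dN), dC = as.numeric(pindel$dC))
}

#' Structure features
#'
#' Min/ave/max disorder probability, three-state secondary-structure
#' probabilities and ASA over the residue window, plus the fractions of
#' predicted coil/helix/strand states in the window (summing to 1).
#'
#' @inheritParams evolution_features
#' @param track An `nfs_residue_track`.
#' @return Named numeric vector of 18 values.
#' @export
structure_features <- function(pindel, track, n_window) {
  if (nrow(track) != pindel$protein_len) {
    stop("Residue track for ", pindel$protein_id, " has ", nrow(track),
         " rows but protein length is ", pindel$protein_len, ".",
         call. = FALSE)
  }
  region <- residue_region(pindel, n_window)
  agg3 <- function(v, nm) {
    stats::setNames(aggregate_window(v), paste(nm, c("min", "ave", "max"),
                                               sep = "_"))
  }
  ss <- track$ss[region]
  c(agg3(track$disorder[region], "disorder"),
    agg3(track$pC[region], "pC"),
    agg3(track$pH[region], "pH"),
    agg3(track$pE[region], "pE"),
    fC = mean(ss == "C"), fH = mean(ss == "H"), fE = mean(ss == "E"),
    agg3(track$asa[region], "asa"))
}

#' Score a sequence against a protein profile
#'
#' Global Viterbi alignment of an amino-acid sequence to the profile's
#' match/insert/delete states. The score is the sum of
#' `log2(emission/background)` over matched residues plus `log2` of every
#' transition probability along the best path; insertions emit at
#' background (log-odds 0) and the begin state uses fixed uniform begin
#' transitions (1/3 over MM/MI/MD; 1/2 over IM/II and DM/DD).
#'
#' @param seq Amino-acid string over the 20-letter alphabet.
#' @param profile An `nfs_profile`.
#' @return Numeric log2-odds alignment score.
#' @export
profile_align_score <- function(seq, profile) {
  res <- strsplit(seq, "")[[1]]
  if (length(res) == 0) stop("Empty sequence.", call. = FALSE)
  idx <- match(res, AA_ALPHABET)
  if (anyNA(idx)) {
    stop("Residue(s) outside the 20-letter alphabet: ",
         paste(unique(res[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  em <- profile$emissions[, idx, drop = FALSE]      # n columns x m residues
  lemit <- log2(sweep(em, 2, profile$background[idx], "/"))
  ltrans <- log2(rbind(begin_transitions(), profile$transitions))
  viterbi_score_cpp(lemit, ltrans)
}

begin_transitions <- function() {
  c(t_MM = 1 / 3, t_MI = 1 / 3, t_MD = 1 / 3,
    t_IM = 1 / 2, t_II = 1 / 2, t_DM = 1 / 2, t_DD = 1 / 2)
}

#' Indel-induced change to the profile match score
#'
#' The whole-protein alignment score of the mutant sequence against the
#' wild-type profile minus that of the wild-type sequence: negative values
#' mean the indel degrades the evolutionary match.
#'
#' @param wt_seq Wild-type protein sequence (the sequence the profile was
#'   built on).
#' @param mut_seq Mutant protein sequence after applying the indel.
#' @param profile An `nfs_profile` for the wild type.
#' @return Numeric `delta_s`.
#' @export
delta_s <- function(wt_seq, mut_seq, profile) {
  if (nchar(wt_seq) != nrow(profile$emissions)) {
    stop("Profile has ", nrow(profile$emissions),
         " columns but wild-type length is ", nchar(wt_seq), ".",
         call. = FALSE)
  }
  profile_align_score(mut_seq, profile) - profile_align_score(wt_seq, profile)
}

#' Reconstruct the mutant protein from transcript and indel
#'
#' Applies the indel to the CDS nucleotides in transcript orientation and
#' translates the result (stop codon removed). Used for the `delta_s`
#' feature and for checking that an NFS indel changes the protein length
#' by exactly its residue count.
#'
#' @inheritParams nucleotide_features
#' @return Mutant amino-acid string.
#' @export
mutant_protein <- function(indel, transcript) {
  cds_seq <- if ("cds_seq" %in% names(transcript)) transcript$cds_seq else NULL
  if (is.null(cds_seq) || is.na(cds_seq)) {
    # no nucleotide sequence available: apply the indel at residue level
    # (valid for codon-aligned indels, which is all the generator emits)
    return(mutant_protein_residues(indel, transcript))
  }
  cdsp <- cds_positions(transcript)
  nt <- strsplit(cds_seq, "")[[1]]
  if (length(nt) != length(cdsp)) {
    stop("cds_seq length does not match CDS coordinates.", call. = FALSE)
  }
  if (indel$kind == "deletion") {
    idx <- match(affected_bases(indel), cdsp)
    nt <- nt[-idx]
  } else {
    c5 <- match(indel$pos, cdsp)
    c3 <- match(indel$pos + 1L, cdsp)
    at <- min(c5, c3)   # insert between transcript positions at, at+1
    ins <- substr(indel$alt, 2, nchar(indel$alt))
    if (transcript$strand == "-") ins <- revcomp(ins)
    nt <- append(nt, strsplit(ins, "")[[1]], after = at)
  }
  coding <- paste(utils::head(nt, length(nt) - 3), collapse = "")
  translate_nt(coding)
}

# residue-level application of a codon-aligned NFS indel
mutant_protein_residues <- function(indel, transcript) {
  pi_ <- map_one(indel, transcript)
  wt <- strsplit(transcript$protein_seq, "")[[1]]
  if (pi_$kind == "deletion") {
    span <- pi_$last_res - pi_$first_res + 1L
    if (span != pi_$n_del) {
      stop("Indel ", indel$id, " is out of codon phase; reconstructing the ",
           "mutant protein requires the transcript's `cds_seq` column.",
           call. = FALSE)
    }
    paste(wt[-seq.int(pi_$first_res, pi_$last_res)], collapse = "")
  } else {
    paste(c(wt[seq_len(pi_$first_res)],
            strsplit(pi_$inserted_aa, "")[[1]],
            wt[seq.int(pi_$first_res + 1L, length(wt))]), collapse = "")
  }
}

#' Assemble the full 58-feature vector for NFS indels
#'
#' Runs every feature group for each NFS-coding indel and binds the result
#' into one row per indel, in the canonical [feature_names()] order, with
#' the site's average relative entropy and conservation stratum appended.
#'
#' @param indels Indel tibble (with `transcript_id`; classified rows other
#'   than `NFS_coding` are rejected).
#' @param transcripts Transcript tibble from [read_transcripts()].
#' @param cons_track Conservation track.
#' @param residue_tracks Named list of `nfs_residue_track`s keyed by
#'   protein id.
#' @param profiles Named list of `nfs_profile`s keyed by protein id.
#' @param n_window Half-window size, 0..7 (default 2, the setting used for
#'   single-feature ranking).
#' @return A tibble: `id`, `label`, the 58 features, `re`, `re_stratum`.
#' @export
assemble_features <- function(indels, transcripts, cons_track,
                              residue_tracks, profiles, n_window = 2) {
  stopifnot(n_window >= 0, n_window <= 7)
  if (is.null(cons_track)) stop("conservation track absent", call. = FALSE)
  pindels <- map_to_protein(indels, transcripts)
  indels <- ensure_transcript_id(indels, transcripts)
  rows <- purrr::map(seq_len(nrow(indels)), function(i) {
    g <- indels[i, ]
    pi_ <- pindels[i, ]
    tx <- transcripts[transcripts$transcript_id == g$transcript_id, ][1, ]
    prof <- profiles[[pi_$protein_id]]
    if (is.null(prof)) {
      stop("profile track absent for protein ", pi_$protein_id, call. = FALSE)
    }
    rtrack <- residue_tracks[[pi_$protein_id]]
    if (is.null(rtrack)) {
      stop("residue structure track absent for protein ", pi_$protein_id,
           call. = FALSE)
    }
    nuc <- nucleotide_features(g, tx, cons_track, n_window)
    evo <- evolution_features(pi_, prof, n_window)
    len <- length_features(pi_)
    ds <- delta_s(tx$protein_seq, mutant_protein(g, tx), prof)
    str_ <- structure_features(pi_, rtrack, n_window)
    re <- site_relative_entropy(pi_, prof)
    vec <- c(nuc, evo, len, delta_s = ds, str_)
    stopifnot(identical(names(vec), as.character(feature_names())))
    tibble::as_tibble(as.list(vec)) |>
      dplyr::mutate(id = g$id, label = g$label, re = re,
                    re_stratum = re_stratify(re), .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' Relative entropy of a site against background
#'
#' `RE = 100 * sum_i p_i log(p_i / q_i)` (natural log) of an amino-acid
#' probability vector `p` against background `q`; the conservation score
#' used to stratify evaluation by site conservation. Terms with `p_i = 0`
#' contribute 0.
#'
#' @param p Length-20 probability vector.
#' @param q Length-20 background probability vector, all positive where
#'   `p > 0`.
#' @return Non-negative numeric; 0 iff `p == q`.
#' @export
relative_entropy <- function(p, q) {
  stopifnot(length(p) == 20, length(q) == 20)
  if (any(q == 0 & p > 0)) {
    stop("Background probability 0 where p > 0; RE undefined.",
         call. = FALSE)
  }
  nz <- p > 0
  100 * sum(p[nz] * log(p[nz] / q[nz]))
}

# average RE over the deleted residues (deletion) or the two residues
# flanking the insertion point, using profile emissions as p
site_relative_entropy <- function(pindel, profile) {
  res <- seq.int(pindel$first_res, pindel$last_res)
  mean(vapply(res, function(r) {
    relative_entropy(profile$emissions[r, ], profile$background)
  }, 0))
}

#' Conservation stratum of a relative-entropy value
#'
#' `high` for RE >= 150, `median` for 70 <= RE < 150, `low` for RE < 70.
#'
#' @param re_value Numeric relative entropy (vectorised).
#' @return Character vector of strata.
#' @export
re_stratify <- function(re_value) {
  dplyr::case_when(re_value >= 150 ~ "high",
                   re_value >= 70 ~ "median",
                   TRUE ~ "low")
}

#' Background amino-acid frequencies of the BLOSUM62 matrix
#'
#' The standard background distribution used as `q` in [relative_entropy()]
#' and as the default profile background.
#'
#' @return Named length-20 numeric vector summing to 1.
#' @export
blosum62_background <- function() {
  stats::setNames(
    c(0.074, 0.025, 0.054, 0.054, 0.047, 0.074, 0.026, 0.068, 0.058, 0.099,
      0.025, 0.045, 0.039, 0.034, 0.052, 0.057, 0.051, 0.073, 0.013, 0.032),
    AA_ALPHABET)
}
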