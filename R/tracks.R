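#' Read a per-base nucleotide conservation track
#'
#' Reads phyloP-style per-base conservation scores from a bedGraph file
#' (0-based half-open intervals) or a fixed-step wiggle, expanding intervals
#' to a 1-based per-base score map. When intervals overlap, the later record
#' wins and a warning is emitted.
#'
#' @param path Path to a bedGraph (`chrom start end score`) or fixedStep
#'   wiggle file.
#' @return A tibble of class `nfs_cons_track` with columns `chrom`, `pos`
#'   (1-based) and `score`.
#' @export
read_conservation <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(structure(tibble::tibble(chrom = character(), pos = integer(),
                                    score = double()),
                     class = c("nfs_cons_track", "tbl_df", "tbl", "data.frame")))
  }
  if (grepl("^fixedStep", lines[1])) {
    tab <- parse_fixedstep_wig(lines)
  } else {
    fields <- stringr::str_split(trimws(lines), "\\s+")
    n_f <- lengths(fields)
    if (any(n_f != 4)) {
      stop("Malformed bedGraph at line ", which(n_f != 4)[1],
           ": expected 4 fields.", call. = FALSE)
    }
    m <- do.call(rbind, fields)
    score <- suppressWarnings(as.numeric(m[, 4]))
    if (anyNA(score)) {
      stop("Non-numeric score in bedGraph at line ", which(is.na(score))[1],
           ".", call. = FALSE)
    }
    start0 <- suppressWarnings(as.integer(m[, 2]))
    end0 <- suppressWarnings(as.integer(m[, 3]))
    if (anyNA(start0) || anyNA(end0)) {
      stop("Non-integer interval bound in bedGraph at line ",
           which(is.na(start0) | is.na(end0))[1], ".", call. = FALSE)
    }
    tab <- tibble::tibble(
      chrom = rep(m[, 1], end0 - start0),
      # 0-based half-open [start, end) -> 1-based positions start+1 .. end
      pos = unlist(purrr::map2(start0 + 1L, end0, seq.int)),
      score = rep(score, end0 - start0)
    )
  }
  dup <- duplicated(tab[, c("chrom", "pos")], fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " overlapping base(s) in conservation track; ",
            "last record wins.", call. = FALSE)
    tab <- tab[!dup, ]
  }
  structure(tab, class = c("nfs_cons_track", class(tibble::tibble())))
}

parse_fixedstep_wig <- function(lines) {
  out <- list()
  chrom <- NULL; pos <- NA_integer_; step <- 1L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^fixedStep", ln)) {
      get <- function(key) {
        m <- stringr::str_match(ln, paste0(key, "=(\\S+)"))[, 2]
        m
      }
      chrom <- get("chrom")
      pos <- as.integer(get("start"))
      step <- as.integer(get("step"))
      if (is.na(step)) step <- 1L
      if (is.na(pos) || is.na(chrom)) {
        stop("Malformed fixedStep header at line ", i, ".", call. = FALSE)
      }
    } else {
      v <- suppressWarnings(as.numeric(ln))
      if (is.na(v)) stop("Non-numeric score in wiggle at line ", i, ".",
                         call. = FALSE)
      out[[length(out) + 1L]] <- tibble::tibble(chrom = chrom, pos = pos,
                                                score = v)
      pos <- pos + step
    }
  }
  dplyr::bind_rows(out)
}

#' Look up conservation scores for a set of bases
#'
#' @param track An `nfs_cons_track`.
#' @param chrom Chromosome name.
#' @param positions 1-based genomic positions.
#' @return Numeric scores in the order of `positions`; errors on any base
#'   absent from the track.
#' @export
conservation_at <- function(track, chrom, positions) {
  sub <- track[track$chrom == chrom, ]
  idx <- match(positions, sub$pos)
  if (anyNA(idx)) {
    stop("Conservation score missing for ", chrom, ":",
         paste(positions[is.na(idx)], collapse = ","), call. = FALSE)
  }
  sub$score[idx]
}

#' Read a per-residue structure prediction track
#'
#' The track carries, for every residue of one protein: the disorder
#' probability (SPINE-D-style), solvent accessible surface area (units
#' declared in the header: absolute Angstrom^2 or relative), three-state
#' secondary-structure probabilities (coil/helix/strand) and the predicted
#' state. Format: a header line `#protein_id <id> len <L> asa_units <abs|rel>`
#' followed by tab-separated rows `pos residue disorder asa pC pH pE ss`.
#'
#' @param path Path to the residue-track TSV.
#' @return A tibble of class `nfs_residue_track` with attributes
#'   `protein_id` and `asa_units`.
#' @export
read_residue_track <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- stringr::str_match(
    lines[1], "^#protein_id\\s+(\\S+)\\s+len\\s+(\\d+)\\s+asa_units\\s+(abs|rel)")
  if (anyNA(hdr)) {
    stop("Residue track ", path, ": malformed header line.", call. = FALSE)
  }
  len <- as.integer(hdr[3])
  tab <- readr::read_tsv(
    I(lines[-1]),
    col_names = c("pos", "residue", "disorder", "asa", "pC", "pH", "pE", "ss"),
    col_types = "icdddddc", progress = FALSE)
  if (nrow(tab) != len) {
    stop("Residue track ", hdr[2], ": ", nrow(tab),
         " rows but declared length ", len, ".", call. = FALSE)
  }
  if (!identical(tab$pos, seq_len(len))) {
    stop("Residue track ", hdr[2], ": positions must run 1..", len, ".",
         call. = FALSE)
  }
  bad_dis <- which(tab$disorder < 0 | tab$disorder > 1)
  if (length(bad_dis) > 0) {
    stop("Residue track ", hdr[2], ": disorder outside [0,1] at row(s) ",
         paste(utils::head(bad_dis, 5), collapse = ","), ".", call. = FALSE)
  }
  ss_sum <- tab$pC + tab$pH + tab$pE
  bad_ss <- which(abs(ss_sum - 1) > 1e-6)
  if (length(bad_ss) > 0) {
    stop("Residue track ", hdr[2],
         ": secondary-structure probabilities do not sum to 1 at row(s) ",
         paste(utils::head(bad_ss, 5), collapse = ","), ".", call. = FALSE)
  }
  bad_state <- which(!tab$ss %in% c("C", "H", "E"))
  if (length(bad_state) > 0) {
    stop("Residue track ", hdr[2], ": predicted state not in {C,H,E} at row(s) ",
         paste(utils::head(bad_state, 5), collapse = ","), ".", call. = FALSE)
  }
  structure(tab, protein_id = hdr[2], asa_units = hdr[4],
            class = c("nfs_residue_track", class(tibble::tibble())))
}

#' Read a protein profile (profile-HMM evolutionary signal)
#'
#' Per-position emission probabilities over the 20 amino acids, the seven
#' position-dependent transition probabilities between match (M),
#' insertion (I) and deletion (D) states (MM, MI, MD, IM, II, DM, DD), and
#' three effective numbers of homologous sequences aligned to match,
#' insertion and deletion states. Format: header `#protein_id <id> len <L>`,
#' a background line `#bg <20 floats>`, then one tab-separated row per
#' column: `pos` + 20 emissions + 7 transitions + 3 n_eff.
#'
#' @param path Path to the profile TSV.
#' @return A list of class `nfs_profile` with elements `protein_id`,
#'   `emissions` (L x 20 matrix, columns named by amino acid), `transitions`
#'   (L x 7 matrix: t_MM, t_MI, t_MD, t_IM, t_II, t_DM, t_DD), `neff`
#'   (L x 3 matrix: neff_M, neff_I, neff_D), `background` (length-20).
#' @export
read_profile <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- stringr::str_match(lines[1], "^#protein_id\\s+(\\S+)\\s+len\\s+(\\d+)")
  if (anyNA(hdr)) stop("Profile ", path, ": malformed header.", call. = FALSE)
  len <- as.integer(hdr[3])
  bg_line <- stringr::str_match(lines[2], "^#bg\\s+(.*)$")[, 2]
  if (is.na(bg_line)) stop("Profile ", hdr[2], ": missing #bg line.",
                           call. = FALSE)
  background <- as.numeric(strsplit(trimws(bg_line), "\\s+")[[1]])
  if (length(background) != 20 || anyNA(background)) {
    stop("Profile ", hdr[2], ": background line must hold 20 numbers.",
         call. = FALSE)
  }
  names(background) <- AA_ALPHABET
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != len) {
    stop("Profile ", hdr[2], ": ", length(body),
         " columns but declared length ", len, ".", call. = FALSE)
  }
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  if (ncol(m) != 31) {
    stop("Profile ", hdr[2], ": each row needs 31 fields ",
         "(pos + 20 emissions + 7 transitions + 3 n_eff).", call. = FALSE)
  }
  emissions <- m[, 2:21, drop = FALSE]
  colnames(emissions) <- AA_ALPHABET
  transitions <- m[, 22:28, drop = FALSE]
  colnames(transitions) <- TRANSITION_NAMES
  neff <- m[, 29:31, drop = FALSE]
  colnames(neff) <- NEFF_NAMES
  bad_em <- which(abs(rowSums(emissions) - 1) > 1e-6)
  if (length(bad_em) > 0) {
    stop("Profile ", hdr[2], ": emissions do not sum to 1 at column(s) ",
         paste(utils::head(bad_em, 5), collapse = ","), ".", call. = FALSE)
  }
  bad_tr <- which(abs(rowSums(transitions[, 1:3, drop = FALSE]) - 1) > 1e-6)
  if (length(bad_tr) > 0) {
    stop("Profile ", hdr[2],
         ": match-state outgoing transitions (MM+MI+MD) do not sum to 1 ",
         "at column(s) ", paste(utils::head(bad_tr, 5), collapse = ","), ".",
         call. = FALSE)
  }
  if (any(transitions < 0 | transitions > 1)) {
    stop("Profile ", hdr[2], ": transition probabilities outside [0,1].",
         call. = FALSE)
  }
  if (any(neff < 0)) {
    stop("Profile ", hdr[2], ": negative n_eff.", call. = FALSE)
  }
  structure(list(protein_id = hdr[2], emissions = emissions,
                 transitions = transitions, neff = neff,
                 background = background),
            class = "nfs_profile")
}

#' @export
print.nfs_profile <- function(x, ...) {
  cat("Protein profile <", x$protein_id, ">: ", nrow(x$emissions),
      " columns, 7 transition probabilities + 3 n_eff per column\n", sep = "")
  invisible(x)
}

# canonical orderings shared across readers, features and the generator
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
TRANSITION_NAMES <- c("t_MM", "t_MI", "t_MD", "t_IM", "t_II", "t_DM", "t_DD")
NEFF_NAMES <- c("neff_M", "neff_I", "neff_D")

#' Window region around a deletion
#'
#' Positions covered when aggregating a track for a deletion: the deleted
#' span plus `n_window` positions on each side, clipped to the sequence.
#' Unclipped, the region holds `n_del + 2*n_window` positions.
#'
#' @param first,last 1-based first and last deleted positions (inclusive).
#' @param n_window Half-window size, 0..7.
#' @param len Sequence length to clip against.
#' @return Integer vector of ordered positions.
#' @export
deletion_region <- function(first, last, n_window, len) {
  stopifnot(first >= 1, last >= first, last <= len, n_window >= 0)
  seq.int(max(1L, first - n_window), min(len, last + n_window))
}

#' Window region around an insertion
#'
#' Positions covered when aggregating a track for an insertion: the two
#' residues (or bases) flanking the insertion point plus `n_window`
#' positions on each side, clipped. Unclipped cardinality is
#' `2 + 2*n_window`.
#'
#' @param flank_i 1-based position of the 5' flank; the 3' flank is
#'   `flank_i + 1`.
#' @inheritParams deletion_region
#' @return Integer vector of ordered positions.
#' @export
insertion_region <- function(flank_i, n_window, len) {
  stopifnot(flank_i >= 1, flank_i < len, n_window >= 0)
  seq.int(max(1L, flank_i - n_window), min(len, flank_i + 1 + n_window))
}

#' Minimum / average / maximum over a window
#'
#' The three summary statistics taken over every windowed track value.
#'
#' @param values Non-empty numeric vector of finite values.
#' @return Named numeric vector `c(min, ave, max)`.
#' @export
aggregate_window <- function(values) {
  if (length(values) == 0) {
    stop("aggregate_window() received an empty window; ",
         "clipping should make this impossible.", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("aggregate_window() requires finite values.", call. = FALSE)
  }
  c(min = min(values), ave = mean(values), max = max(values))
}
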