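#' Read micro-indels from a VCF file
#'
#' Parses a VCF 4.x file and returns pure insertion/deletion records
#' (reference and alternate alleles of unequal length, sharing the anchor
#' base). Multi-allelic records are split into one row per alternate
#' allele. SNVs, MNVs of equal length and symbolic alleles are skipped; the
#' skip count is reported in a message and attached as attribute
#' `n_skipped`.
#'
#' @param path Path to a VCF file.
#' @param label_key INFO key carrying the class label
#'   (`disease`/`neutral`); default `"LABEL"`.
#' @param maf_key INFO key carrying the minor allele frequency; default
#'   `"AF"`.
#' @return A tibble with columns `id`, `chrom`, `pos` (1-based anchor),
#'   `ref`, `alt`, `kind` (`insertion`/`deletion`), `net_len`, `label`
#'   (`disease`/`neutral`/`unknown`) and `maf` (NA when absent).
#' @export
read_vcf <- function(path, label_key = "LABEL", maf_key = "AF") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble::tibble(id = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), kind = character(),
                          net_len = integer(), label = character(),
                          maf = double()))
  }
  info_field <- function(info, key) {
    stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
  }
  rows <- purrr::pmap(fix, function(CHROM, POS, ID, REF, ALT, QUAL, FILTER,
                                    INFO, ...) {
    alts <- strsplit(ALT, ",", fixed = TRUE)[[1]]
    lab <- info_field(INFO, label_key)
    maf <- suppressWarnings(as.numeric(info_field(INFO, maf_key)))
    tibble::tibble(id = ifelse(is.na(ID) | ID == ".",
                               paste0(CHROM, ":", POS), ID),
                   chrom = CHROM, pos = as.integer(POS), ref = REF,
                   alt = alts,
                   label = ifelse(is.na(lab), "unknown", lab),
                   maf = ifelse(is.na(maf), NA_real_, maf))
  })
  tab <- dplyr::bind_rows(rows)
  symbolic <- grepl("[<>\\[\\]*]", tab$alt) | grepl("[<>\\[\\]*]", tab$ref)
  is_indel <- !symbolic & nchar(tab$ref) != nchar(tab$alt)
  n_skipped <- sum(!is_indel)
  if (n_skipped > 0) {
    message("read_vcf: skipped ", n_skipped,
            " non-indel record(s) (SNV/MNV/symbolic).")
  }
  tab <- tab[is_indel, ]
  bad_maf <- !is.na(tab$maf) & (tab$maf < 0 | tab$maf > 1)
  if (any(bad_maf)) {
    stop("MAF outside [0,1] for record(s): ",
         paste(tab$id[bad_maf], collapse = ", "), call. = FALSE)
  }
  out <- dplyr::mutate(
    tab,
    kind = ifelse(nchar(.data$ref) > nchar(.data$alt), "deletion",
                  "insertion"),
    net_len = abs(nchar(.data$ref) - nchar(.data$alt))
  )
  # flag non-normalized alleles (anchor base not shared) without altering them
  anchor_ok <- substr(out$ref, 1, 1) == substr(out$alt, 1, 1)
  if (any(!anchor_ok)) {
    warning("read_vcf: ", sum(!anchor_ok),
            " record(s) have non-shared anchor bases; alleles are used ",
            "as given (no left-alignment is performed).", call. = FALSE)
  }
  out <- dplyr::select(out, "id", "chrom", "pos", "ref", "alt", "kind",
                       "net_len", "label", "maf")
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read transcript models from GTF plus a protein FASTA
#'
#' Collects `exon` and `CDS` features per `transcript_id` and joins each
#' transcript to its protein sequence by `protein_id`. The CDS here
#' includes the stop codon, so a valid transcript satisfies
#' `cds length = 3 * (protein_len + 1)`. Transcripts violating the model
#' invariants (unsorted/overlapping exons, CDS length not divisible by 3,
#' CDS/protein length mismatch, missing protein sequence) are dropped with
#' a message naming the reason.
#'
#' @param gtf_path GTF file with exon and CDS features carrying
#'   `transcript_id` and `protein_id` attributes.
#' @param fasta_path FASTA of protein sequences keyed by `protein_id`.
#' @return A tibble with one row per usable transcript: `transcript_id`,
#'   `chrom`, `strand`, `protein_id`, `protein_seq`, `protein_len`, and
#'   list-columns `exons` and `cds` (tibbles of 1-based inclusive `start`,
#'   `end`).
#' @export
read_transcripts <- function(gtf_path, fasta_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  aa <- Biostrings::readAAStringSet(fasta_path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  df <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    transcript_id = gr$transcript_id,
    protein_id = if (!is.null(gr$protein_id)) gr$protein_id else NA_character_
  )
  df <- dplyr::filter(df, .data$type %in% c("exon", "CDS"),
                      !is.na(.data$transcript_id))
  out <- list()
  for (tid in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == tid, ]
    exons <- dplyr::arrange(sub[sub$type == "exon", c("start", "end")],
                            .data$start)
    cds <- dplyr::arrange(sub[sub$type == "CDS", c("start", "end")],
                          .data$start)
    pid <- stats::na.omit(unique(sub$protein_id))[1]
    reason <- transcript_problem(exons, cds, pid, aa)
    if (!is.null(reason)) {
      message("read_transcripts: dropping ", tid, ": ", reason)
      next
    }
    out[[tid]] <- tibble::tibble(
      transcript_id = tid,
      chrom = sub$chrom[1],
      strand = sub$strand[1],
      protein_id = pid,
      protein_seq = as.character(aa[[pid]]),
      protein_len = nchar(as.character(aa[[pid]])),
      exons = list(exons),
      cds = list(cds)
    )
  }
  dplyr::bind_rows(out)
}

transcript_problem <- function(exons, cds, pid, aa) {
  if (nrow(exons) == 0) return("no exon features")
  if (nrow(cds) == 0) return("no CDS features")
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    return("overlapping or unsorted exons")
  }
  cds_len <- sum(cds$end - cds$start + 1)
  if (cds_len %% 3 != 0) {
    return(paste0("CDS length ", cds_len, " not divisible by 3"))
  }
  if (is.na(pid) || !pid %in% names(aa)) {
    return("missing protein sequence")
  }
  plen <- nchar(as.character(aa[[pid]]))
  if (cds_len != 3 * (plen + 1)) {
    return(paste0("CDS length ", cds_len, " inconsistent with protein ",
                  "length ", plen, " (expected ", 3 * (plen + 1),
                  " including stop)"))
  }
  NULL
}

# Genomic positions of the CDS in translation (transcript) order.
cds_positions <- function(transcript) {
  cds <- transcript$cds[[1]]
  pos <- unlist(purrr::map2(cds$start, cds$end, seq.int))
  if (transcript$strand == "-") rev(pos) else pos
}

# 1-based genomic positions affected by an indel: the deleted bases, or the
# two bases flanking an insertion point (anchor base and its right
# neighbour on the genome).
affected_bases <- function(indel) {
  if (indel$kind == "deletion") {
    seq.int(indel$pos + 1L, indel$pos + indel$net_len)
  } else {
    c(indel$pos, indel$pos + 1L)
  }
}

classify_one <- function(indel, transcript) {
  cdsp <- cds_positions(transcript)
  stop_pos <- utils::tail(cdsp, 3)           # stop codon, transcript order
  coding_pos <- utils::head(cdsp, -3)        # translated positions
  exons <- transcript$exons[[1]]
  in_exon <- function(p) any(p >= exons$start & p <= exons$end)
  aff <- affected_bases(indel)
  if (indel$kind == "deletion") {
    if (any(aff %in% stop_pos)) return("stop_overlap")
    if (all(aff %in% coding_pos)) {
      return(if (indel$net_len %% 3 == 0) "NFS_coding" else "FS_coding")
    }
    within_tx <- aff >= min(exons$start) & aff <= max(exons$end)
    if (all(within_tx) && !any(vapply(aff, in_exon, TRUE))) return("intronic")
    return("noncoding")
  }
  # insertion: point between aff[1] and aff[2]
  if (all(aff %in% cdsp)) {
    idx <- match(aff, cdsp)
    if (max(idx) > length(coding_pos)) return("stop_overlap")
    if (abs(diff(idx)) != 1) return("noncoding")  # spliced-out junction
    return(if (indel$net_len %% 3 == 0) "NFS_coding" else "FS_coding")
  }
  within_tx <- aff >= min(exons$start) & aff <= max(exons$end)
  if (all(within_tx) && !any(vapply(aff, in_exon, TRUE))) return("intronic")
  "noncoding"
}

#' Classify indels against their transcript
#'
#' Partitions each indel into exactly one of `NFS_coding`, `FS_coding`,
#' `intronic`, `stop_overlap` or `noncoding`. An indel is non-frameshifting
#' coding when every affected base lies in the translated CDS, its net
#' length is a multiple of 3, and the stop codon is untouched; any overlap
#' with the stop codon takes precedence.
#'
#' @param indels Tibble from [read_vcf()], with a `transcript_id` column
#'   naming the host transcript (may be omitted when `transcripts` has a
#'   single row).
#' @param transcripts Tibble from [read_transcripts()].
#' @return `indels` with an added `category` column.
#' @export
classify_indels <- function(indels, transcripts) {
  indels <- ensure_transcript_id(indels, transcripts)
  cat <- purrr::map_chr(seq_len(nrow(indels)), function(i) {
    tx <- transcripts[transcripts$transcript_id == indels$transcript_id[i], ]
    if (nrow(tx) == 0) {
      stop("Unknown transcript_id '", indels$transcript_id[i],
           "' for indel ", indels$id[i], ".", call. = FALSE)
    }
    if (tx$chrom[1] != indels$chrom[i]) {
      stop("Indel ", indels$id[i], " is on ", indels$chrom[i],
           " but transcript ", tx$transcript_id[1], " is on ", tx$chrom[1],
           ".", call. = FALSE)
    }
    classify_one(indels[i, ], tx[1, ])
  })
  dplyr::mutate(indels, category = cat)
}

ensure_transcript_id <- function(indels, transcripts) {
  if (!"transcript_id" %in% names(indels)) {
    if (nrow(transcripts) == 1) {
      indels$transcript_id <- transcripts$transcript_id[1]
    } else {
      stop("`indels` needs a transcript_id column when more than one ",
           "transcript is supplied.", call. = FALSE)
    }
  }
  indels
}

map_one <- function(indel, transcript) {
  cdsp <- cds_positions(transcript)
  plen <- transcript$protein_len
  aff <- affected_bases(indel)
  idx <- match(aff, cdsp)
  if (anyNA(idx)) {
    stop("Indel ", indel$id, " affects bases outside the CDS; ",
         "only NFS_coding indels can be mapped.", call. = FALSE)
  }
  d <- splice_distances_one(indel, transcript)
  if (indel$kind == "deletion") {
    c1 <- min(idx); c2 <- max(idx)
    if (c2 - c1 + 1 != indel$net_len) {
      stop("Indel ", indel$id, ": deleted bases are not contiguous in CDS ",
           "coordinates; codon-phase-consistent mapping impossible.",
           call. = FALSE)
    }
    first_res <- ceiling(c1 / 3)
    last_res <- ceiling(c2 / 3)
    tibble::tibble(
      id = indel$id, protein_id = transcript$protein_id,
      kind = "deletion",
      first_res = as.integer(first_res), last_res = as.integer(last_res),
      n_del = as.integer(indel$net_len / 3),
      inserted_aa = NA_character_,
      d5 = d[1], d3 = d[2],
      dN = as.integer(first_res - 1), dC = as.integer(plen - last_res),
      protein_len = as.integer(plen)
    )
  } else {
    c5 <- min(idx)
    flank_i <- min(ceiling(c5 / 3), plen - 1L)
    ins_nt <- substr(indel$alt, 2, nchar(indel$alt))
    if (transcript$strand == "-") ins_nt <- revcomp(ins_nt)
    ins_aa <- translate_nt(ins_nt)
    tibble::tibble(
      id = indel$id, protein_id = transcript$protein_id,
      kind = "insertion",
      first_res = as.integer(flank_i), last_res = as.integer(flank_i + 1),
      n_del = as.integer(indel$net_len / 3),
      inserted_aa = ins_aa,
      d5 = d[1], d3 = d[2],
      dN = as.integer(flank_i - 1), dC = as.integer(plen - flank_i),
      protein_len = as.integer(plen)
    )
  }
}

#' Map NFS-coding indels to protein coordinates
#'
#' For a deletion, the residue span covers every codon with at least one
#' deleted base (`first_res`..`last_res`); `n_del = net_len / 3` counts
#' whole residues removed (the span can exceed `n_del` by one when the
#' deletion is out of codon phase; the substituted junction residue is not
#' treated as deleted). For an insertion, `first_res`/`last_res` are the
#' two flanking residues. Distances to the host exon's splice boundaries
#' (`d5`, `d3`, bases) and to the protein termini (`dN`, `dC`, residues)
#' are attached.
#'
#' @inheritParams classify_indels
#' @return A tibble of protein indels: `id`, `protein_id`, `kind`,
#'   `first_res`, `last_res`, `n_del`, `inserted_aa`, `d5`, `d3`, `dN`,
#'   `dC`, `protein_len`.
#' @export
map_to_protein <- function(indels, transcripts) {
  indels <- ensure_transcript_id(indels, transcripts)
  if (!"category" %in% names(indels)) {
    indels <- classify_indels(indels, transcripts)
  }
  if (any(indels$category != "NFS_coding")) {
    stop("map_to_protein() accepts NFS_coding indels only; got ",
         paste(unique(indels$category[indels$category != "NFS_coding"]),
               collapse = ", "), ".", call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(indels)), function(i) {
    tx <- transcripts[transcripts$transcript_id == indels$transcript_id[i], ]
    map_one(indels[i, ], tx[1, ])
  })
}

splice_distances_one <- function(indel, transcript) {
  exons <- transcript$exons[[1]]
  aff <- affected_bases(indel)
  host <- which(min(aff) >= exons$start & max(aff) <= exons$end)
  if (length(host) == 0) {
    stop("Indel ", indel$id, " spans an exon boundary; cannot assign a ",
         "single host exon for splice distances.", call. = FALSE)
  }
  ex <- exons[host[1], ]
  if (transcript$strand == "+") {
    d5 <- min(aff) - ex$start
    d3 <- ex$end - max(aff)
  } else {
    d5 <- ex$end - max(aff)
    d3 <- min(aff) - ex$start
  }
  c(d5 = as.integer(d5), d3 = as.integer(d3))
}

#' Distances from an indel to its exon's splice boundaries
#'
#' `d5` is the distance (bases) from the 5'-most affected base to the host
#' exon's 5' boundary in transcript orientation; `d3` the distance from the
#' 3'-most affected base to the 3' boundary. On the minus strand the
#' genomic left/right boundary roles swap. Single-exon transcripts use the
#' transcript ends as boundaries.
#'
#' @inheritParams classify_indels
#' @return `indels` with added integer columns `d5` and `d3`.
#' @export
splice_distances <- function(indels, transcripts) {
  indels <- ensure_transcript_id(indels, transcripts)
  d <- purrr::map(seq_len(nrow(indels)), function(i) {
    tx <- transcripts[transcripts$transcript_id == indels$transcript_id[i], ]
    splice_distances_one(indels[i, ], tx[1, ])
  })
  dplyr::mutate(indels,
                d5 = purrr::map_int(d, 1),
                d3 = purrr::map_int(d, 2))
}

#' Do a micro-insertion and a micro-deletion share a site?
#'
#' True when at least one of the two residues flanking the insertion lies
#' within the deleted residue span — the overlap rule used to decide
#' whether insertion and deletion sets are independent.
#'
#' @param ins One-row protein-indel tibble with `kind == "insertion"`.
#' @param del One-row protein-indel tibble with `kind == "deletion"`.
#' @return Logical scalar; `FALSE` (not an error) for different proteins.
#' @export
sites_overlap <- function(ins, del) {
  stopifnot(ins$kind == "insertion", del$kind == "deletion")
  if (ins$protein_id != del$protein_id) return(FALSE)
  any(c(ins$first_res, ins$last_res) >= del$first_res &
        c(ins$first_res, ins$last_res) <= del$last_res)
}

# small nucleotide helpers (generator + mapping share them)
revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

translate_nt <- function(nt) {
  if (nchar(nt) %% 3 != 0) {
    stop("Cannot translate a sequence of length ", nchar(nt), ".",
         call. = FALSE)
  }
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     no.init.codon = TRUE))
}
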