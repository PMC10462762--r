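# Demultiplexing paired-end amplicon reads into per-clone counts.
#
# Each forward read carries both SDB regions, each bracketed by constant
# flanks. Extraction finds the upstream flank (exact scan first, then a
# Hamming scan tolerating up to `max_flank_mismatch` substitutions; the
# leftmost hit wins) and takes the fixed-length barcode immediately after it.

#' Describe the amplicon layout of a LiGA sequencing run
#'
#' @param upstream1,downstream1 Constant flanks bracketing SDB1 on the
#'   forward read.
#' @param upstream2,downstream2 Flanks bracketing SDB2.
#' @param sdb1_len,sdb2_len Barcode lengths (nt).
#' @param read_length Read length in cycles (2 x 75 bp chemistry by default).
#' @param sample_index_map Optional named character vector mapping index
#'   barcodes to sample names (unused when reads are already split per
#'   sample, the layout this package's simulator produces).
#' @return Object of class `amplicon_design`.
#' @export
amplicon_design <- function(upstream1 = "ACCTCGAG", downstream1 = "GGTACCAA",
                            upstream2 = "TTGCATGC", downstream2 = "CCATGGTT",
                            sdb1_len = 9L, sdb2_len = 6L,
                            read_length = 75L, sample_index_map = NULL) {
  flanks <- c(upstream1, downstream1, upstream2, downstream2)
  if (any(!nzchar(flanks)) || any(!grepl("^[ACGT]+$", flanks)))
    stop("flanks must be non-empty ACGT strings")
  if (sdb1_len <= 0 || sdb2_len <= 0) stop("sdb lengths must be positive")
  structure(list(upstream1 = upstream1, downstream1 = downstream1,
                 upstream2 = upstream2, downstream2 = downstream2,
                 sdb1_len = as.integer(sdb1_len), sdb2_len = as.integer(sdb2_len),
                 read_length = as.integer(read_length),
                 sample_index_map = sample_index_map),
            class = "amplicon_design")
}

# Leftmost occurrence of `flank` in `seq` allowing up to `max_mm` Hamming
# mismatches, starting the scan at `from` (1-based). Returns start position
# or NA. Exact matches are preferred at any position over inexact ones.
find_flank <- function(seq, flank, max_mm = 0L, from = 1L) {
  n <- nchar(seq); k <- nchar(flank)
  if (from + k - 1L > n) return(NA_integer_)
  hit <- regexpr(flank, substr(seq, from, n), fixed = TRUE)
  exact <- if (hit > 0) from + as.integer(hit) - 1L else NA_integer_
  if (max_mm == 0L || (!is.na(exact) && exact == from)) return(exact)
  fl <- strsplit(flank, "")[[1]]
  last <- if (is.na(exact)) n - k + 1L else exact  # nothing left of an exact hit beats it
  for (pos in from:last) {
    if (!is.na(exact) && pos == exact) return(exact)
    window <- strsplit(substr(seq, pos, pos + k - 1L), "")[[1]]
    if (sum(window != fl) <= max_mm) return(pos)
  }
  exact
}

#' Extract the silent double barcode from a read
#'
#' @param read Forward-read sequence (character scalar).
#' @param design An [amplicon_design()].
#' @param max_flank_mismatch Hamming mismatches tolerated per flank.
#' @return List with `sdb1`, `sdb2` and the concatenated `barcode`, or `NULL`
#'   when either region cannot be located (failure is data, not an error).
#' @export
extract_sdb <- function(read, design, max_flank_mismatch = 0L) {
  n <- nchar(read)

  grab <- function(up, down, len, from) {
    pos <- find_flank(read, up, max_flank_mismatch, from)
    if (is.na(pos)) return(NULL)
    bc_start <- pos + nchar(up)
    bc_end <- bc_start + len - 1L
    if (bc_end > n) return(NULL)  # barcode runs off the read
    # verify the downstream flank when it fully fits on the read
    dn_end <- bc_end + nchar(down)
    if (dn_end <= n) {
      obs <- substr(read, bc_end + 1L, dn_end)
      mm <- sum(strsplit(obs, "")[[1]] != strsplit(down, "")[[1]])
      if (mm > max_flank_mismatch) return(NULL)
    }
    list(barcode = substr(read, bc_start, bc_end), next_pos = dn_end + 1L)
  }

  r1 <- grab(design$upstream1, design$downstream1, design$sdb1_len, 1L)
  if (is.null(r1)) return(NULL)
  r2 <- grab(design$upstream2, design$downstream2, design$sdb2_len, r1$next_pos)
  if (is.null(r2)) return(NULL)
  list(sdb1 = r1$barcode, sdb2 = r2$barcode,
       barcode = paste0(r1$barcode, r2$barcode))
}

#' Map an extracted barcode to a dictionary entry
#'
#' Exact matches are preferred; with `max_mismatch = 1` a barcode that has a
#' unique Hamming-1 neighbour in the dictionary is rescued. Ties or larger
#' distances are unmapped (the read is discarded).
#'
#' @param barcode Concatenated SDB1+SDB2 string.
#' @param dict A `liga_dictionary`.
#' @param max_mismatch 0 (default, no error correction) or 1.
#' @return The matching `entry_id`, or `NA_character_` if unmapped.
#' @export
map_entry <- function(barcode, dict, max_mismatch = 0L) {
  bcs <- dictionary_barcodes(dict)
  if (!length(bcs)) stop("dictionary is empty")
  hit <- match(barcode, bcs)
  if (!is.na(hit)) return(names(bcs)[hit])
  if (max_mismatch >= 1L) {
    cand <- bcs[nchar(bcs) == nchar(barcode)]
    if (length(cand)) {
      q <- strsplit(barcode, "")[[1]]
      d <- vapply(strsplit(cand, ""), function(s) sum(s != q), integer(1))
      near <- which(d <= max_mismatch)
      if (length(near) == 1L) return(names(cand)[near])
    }
  }
  NA_character_
}

# FASTQ sequences as a character vector (gz-transparent). Parsing is done by
# Biostrings; on failure the file is re-scanned line-wise so the error can
# name the offending record.
read_fastq_sequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)  # also used for the empty-file and diagnostics paths
  if (length(lines) == 0L) return(character())
  heads <- lines[seq(1, length(lines), by = 4)]
  seps <- if (length(lines) >= 3) lines[seq(3, length(lines), by = 4)] else character()
  bad <- which(!startsWith(heads, "@") | is.na(seps[seq_along(heads)]) |
                 !startsWith(seps[seq_along(heads)], "+"))
  if (length(lines) %% 4L != 0L)
    bad <- c(bad, (length(lines) %/% 4L) + 1L)
  if (length(bad))
    stop(sprintf("malformed FASTQ record %d in %s", min(bad), path))
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = FALSE),
    error = function(e) stop(sprintf("malformed FASTQ %s: %s", path, conditionMessage(e))))
  as.character(seqs, use.names = FALSE)
}

#' Count reads per dictionary entry and sample
#'
#' Runs [extract_sdb()] and [map_entry()] over every forward read of every
#' sample and tallies reads per entry. Reads whose barcode cannot be located
#' or mapped are counted as unmapped and discarded; per-sample bookkeeping
#' satisfies mapped + unmapped = total.
#'
#' @param fastq_r1 Named character vector of forward-read FASTQ paths, one
#'   per sample (names become sample names).
#' @param design An [amplicon_design()].
#' @param dict A `liga_dictionary`.
#' @param fastq_r2 Optional mate files (pass-through only; the reverse read
#'   carries no SDB region in this layout).
#' @param max_flank_mismatch,max_mismatch See [extract_sdb()], [map_entry()].
#' @return A `liga_counts` object: integer matrix (entries x samples) with a
#'   `totals` attribute (`data.frame` of total/mapped/unmapped/unassigned_index
#'   per sample).
#' @export
count_reads <- function(fastq_r1, design, dict, fastq_r2 = NULL,
                        max_flank_mismatch = 0L, max_mismatch = 0L) {
  if (is.null(names(fastq_r1)) || any(!nzchar(names(fastq_r1))))
    stop("`fastq_r1` must be named by sample")
  samples <- names(fastq_r1)
  entry_ids <- dict$entries$entry_id
  bcs <- dictionary_barcodes(dict)
  mat <- matrix(0L, nrow = length(entry_ids), ncol = length(samples),
                dimnames = list(entry_ids, samples))
  totals <- data.frame(sample = samples, total = 0L, mapped = 0L,
                       unmapped = 0L, unassigned_index = 0L,
                       stringsAsFactors = FALSE)

  for (j in seq_along(samples)) {
    reads <- read_fastq_sequences(fastq_r1[[j]])
    totals$total[j] <- length(reads)
    if (!length(reads)) next
    extracted <- vapply(reads, function(r) {
      hit <- extract_sdb(r, design, max_flank_mismatch)
      if (is.null(hit)) NA_character_ else hit$barcode
    }, character(1), USE.NAMES = FALSE)
    # exact lookups vectorised; Hamming-1 rescue entry by entry
    idx <- match(extracted, bcs)
    if (max_mismatch >= 1L) {
      miss <- which(is.na(idx) & !is.na(extracted))
      for (k in miss) {
        eid <- map_entry(extracted[k], dict, max_mismatch)
        if (!is.na(eid)) idx[k] <- match(eid, entry_ids)
      }
    }
    tab <- table(factor(entry_ids[idx[!is.na(idx)]], levels = entry_ids))
    mat[, j] <- as.integer(tab)
    totals$mapped[j] <- sum(mat[, j])
    totals$unmapped[j] <- totals$total[j] - totals$mapped[j]
  }
  liga_counts(mat, totals)
}

#' Construct a `liga_counts` matrix
#' @param mat Integer matrix, entries x samples.
#' @param totals Per-sample bookkeeping `data.frame` (sample, total, mapped,
#'   unmapped, unassigned_index); derived from `mat` when omitted.
#' @export
liga_counts <- function(mat, totals = NULL) {
  if (any(mat < 0)) stop("counts must be non-negative")
  storage.mode(mat) <- "integer"
  if (is.null(totals))
    totals <- data.frame(sample = colnames(mat), total = colSums(mat),
                         mapped = colSums(mat), unmapped = 0L,
                         unassigned_index = 0L, stringsAsFactors = FALSE)
  stopifnot(all(totals$mapped + totals$unmapped == totals$total))
  structure(mat, totals = totals, class = c("liga_counts", class(mat)))
}

#' @export
print.liga_counts <- function(x, ...) {
  t <- attr(x, "totals")
  cat(sprintf("LiGA counts: %d entries x %d samples; mapped %d / %d reads\n",
              nrow(x), ncol(x), sum(t$mapped), sum(t$total)))
  invisible(x)
}

#' Write a count matrix as TSV with a JSON sidecar of per-sample totals
#' @param counts A `liga_counts`.
#' @param path Output TSV path; the sidecar is written at `<path>.totals.json`.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(entry_id = rownames(counts), as.data.frame(unclass(counts)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(attr(counts, "totals"),
                       paste0(path, ".totals.json"), dataframe = "rows")
  invisible(path)
}

#' Read a count matrix written by [write_counts()]
#' @param path TSV path.
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$entry_id
  sidecar <- paste0(path, ".totals.json")
  totals <- if (file.exists(sidecar))
    as.data.frame(jsonlite::read_json(sidecar, simplifyVector = TRUE))
  else NULL
  liga_counts(mat, totals)
}
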