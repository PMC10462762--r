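# LiGA dictionaries: the lookup tables translating silent double barcodes
# (SDBs) in the phage genome to glycan structures and mean display densities.

#' Monosaccharide residue masses (Da, monoisotopic)
#'
#' Residue (dehydrated) masses used to predict conjugate masses from a glycan
#' composition.
#' @export
RESIDUE_MASSES <- c(Hex = 162.0528, HexNAc = 203.0794,
                    Neu5Ac = 291.0954, dHex = 146.0579)

#' Number of pVIII coat proteins available for modification per virion
#' @export
AVAILABLE_PVIII <- 2700L

#' Describe a glycan structure
#'
#' @param structure_id Short unique identifier (e.g. `"A2G2S2"`).
#' @param cfg_name Abbreviated name following Consortium for Functional
#'   Glycomics nomenclature.
#' @param composition Named integer vector of monosaccharide-class counts;
#'   names must be a subset of `names(RESIDUE_MASSES)`.
#' @param terminal_tags Character vector of terminal epitopes
#'   (e.g. `"Neu5Ac-a2,6"`, `"Gal"`, `"GlcNAc"`).
#' @return An object of class `glycan_structure`.
#' @export
glycan_structure <- function(structure_id, cfg_name = structure_id,
                             composition = integer(), terminal_tags = character()) {
  composition <- unlist(composition)
  if (length(composition)) {
    bad <- setdiff(names(composition), names(RESIDUE_MASSES))
    if (length(bad)) stop("unknown monosaccharide class: ", paste(bad, collapse = ", "))
    if (any(composition < 0)) stop("composition counts must be >= 0")
  }
  structure(list(structure_id = structure_id, cfg_name = cfg_name,
                 composition = composition, terminal_tags = terminal_tags),
            class = "glycan_structure")
}

#' Parse a composition string such as "Hex:5;HexNAc:4;Neu5Ac:2"
#' @param x Character scalar ("" for none).
#' @return Named integer vector.
#' @export
parse_composition <- function(x) {
  if (is.na(x) || !nzchar(x)) return(stats::setNames(integer(), character()))
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  counts <- vapply(kv, function(p) as.integer(p[2]), integer(1))
  names(counts) <- vapply(kv, `[`, character(1), 1)
  if (anyNA(counts) || any(counts < 0)) stop("malformed composition string: ", x)
  counts
}

#' @rdname parse_composition
#' @param counts Named integer vector.
#' @export
format_composition <- function(counts) {
  if (!length(counts)) return("")
  paste(sprintf("%s:%d", names(counts), as.integer(counts)), collapse = ";")
}

DICT_COLUMNS <- c("entry_id", "library_id", "sdb1", "sdb2",
                  "modification_class", "structure_id", "cfg_name",
                  "composition", "mean_density")
MOD_CLASSES <- c("glycan", "azidoethanol", "unmodified")

#' Construct a LiGA dictionary
#'
#' A dictionary maps silent double barcodes (SDB1 + SDB2, concatenated for
#' lookup) to the glycan structure and mean display density of each phage
#' clone in a LiGA mixture. Barcodes are "silent": all variants encode the
#' same peptide in the phage genome (default `SVEKY`).
#'
#' @param entries `data.frame` with columns `entry_id`, `library_id`, `sdb1`,
#'   `sdb2`, `modification_class` (one of glycan/azidoethanol/unmodified),
#'   `structure_id`, `cfg_name`, `composition` (string form), `mean_density`
#'   (glycans/virion, 0 for non-glycan classes).
#' @param library_id Two-letter library code.
#' @param available_pviii Copies of pVIII available per virion (2700).
#' @param sdb_offset 0-based frame offset of the silent coding region within
#'   the concatenated barcode.
#' @param expected_peptide Peptide every barcode must encode.
#' @param validate Run silent-coding validation on construction.
#' @return Object of class `liga_dictionary`.
#' @export
liga_dictionary <- function(entries, library_id = "XX",
                            available_pviii = AVAILABLE_PVIII,
                            sdb_offset = 0L, expected_peptide = "SVEKY",
                            validate = FALSE) {
  if (!is.data.frame(entries)) stop("`entries` must be a data.frame")
  missing_cols <- setdiff(DICT_COLUMNS, names(entries))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  entries <- as.data.frame(entries[, DICT_COLUMNS], stringsAsFactors = FALSE)
  rownames(entries) <- NULL

  if (anyDuplicated(entries$entry_id))
    stop("duplicate entry_id")
  bc <- paste0(entries$sdb1, entries$sdb2)
  if (anyDuplicated(bc))
    stop("duplicate barcode: ",
         paste(unique(bc[duplicated(bc)]), collapse = ", "))
  if (length(bc) && any(!grepl("^[ACGT]+$", bc)))
    stop("non-ACGT barcode in entries: ",
         paste(entries$entry_id[!grepl("^[ACGT]+$", bc)], collapse = ", "))
  if (any(entries$mean_density < 0))
    stop("negative density for entry ",
         paste(entries$entry_id[entries$mean_density < 0], collapse = ", "))
  if (any(entries$mean_density > available_pviii))
    stop("mean_density exceeds available pVIII copies")
  if (any(!entries$modification_class %in% MOD_CLASSES))
    stop("modification_class must be one of ", paste(MOD_CLASSES, collapse = "/"))
  nonglycan <- entries$modification_class != "glycan"
  if (any(!nonglycan & (is.na(entries$structure_id) | !nzchar(entries$structure_id))))
    stop("glycan entries must reference a structure_id")
  if (any(nonglycan & entries$mean_density != 0))
    stop("non-glycan entries must have mean_density 0")

  obj <- list(entries = entries, library_id = library_id,
              available_pviii = as.integer(available_pviii),
              sdb_region = list(offset = as.integer(sdb_offset),
                                expected_peptide = expected_peptide))
  class(obj) <- "liga_dictionary"
  if (validate) {
    rep <- validate_silent_coding(obj)
    if (!attr(rep, "pass"))
      stop("silent-coding validation failed for: ",
           paste(rep$entry_id[!rep$pass], collapse = ", "))
  }
  obj
}

#' @export
print.liga_dictionary <- function(x, ...) {
  tab <- table(x$entries$modification_class)
  cat(sprintf("LiGA dictionary '%s': %d entries (%s); %d pVIII/virion; peptide %s\n",
              x$library_id, nrow(x$entries),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              x$available_pviii, x$sdb_region$expected_peptide))
  invisible(x)
}

#' Concatenated barcode keys of a dictionary
#' @param dict A `liga_dictionary`.
#' @return Named character vector (names = entry ids).
#' @export
dictionary_barcodes <- function(dict) {
  stats::setNames(paste0(dict$entries$sdb1, dict$entries$sdb2),
                  dict$entries$entry_id)
}

#' Read a LiGA dictionary from delimited text
#'
#' The canonical dialect is UTF-8 TSV with `#key=value` metadata header lines
#' (written by [write_liga_dictionary()]); comma-delimited files with the same
#' columns are also accepted via `sep = ","`.
#'
#' @param path File path.
#' @param sep Field separator (tab default).
#' @return A `liga_dictionary`.
#' @export
read_liga_dictionary <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (m in sub("^#", "", meta_lines)) {
    kv <- strsplit(m, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (nrow(df)) df$mean_density <- as.numeric(df$mean_density)
  else df$mean_density <- numeric()
  liga_dictionary(df,
                  library_id = meta$library_id %||% "XX",
                  available_pviii = as.integer(meta$available_pviii %||% AVAILABLE_PVIII),
                  sdb_offset = as.integer(meta$sdb_offset %||% 0L),
                  expected_peptide = meta$expected_peptide %||% "SVEKY")
}

#' Write a LiGA dictionary (canonical TSV dialect)
#'
#' Round-trips byte-identically with [read_liga_dictionary()].
#' @param dict A `liga_dictionary`.
#' @param path Output path.
#' @export
write_liga_dictionary <- function(dict, path) {
  con <- file(path, open = "wb")  # "wb": byte-stable line endings
  on.exit(close(con))
  meta <- sprintf("#%s=%s",
                  c("library_id", "available_pviii", "sdb_offset", "expected_peptide"),
                  c(dict$library_id, dict$available_pviii,
                    dict$sdb_region$offset, dict$sdb_region$expected_peptide))
  writeLines(meta, con, sep = "\n")
  df <- dict$entries
  df$mean_density <- format(df$mean_density, trim = TRUE, scientific = FALSE)
  writeLines(paste(DICT_COLUMNS, collapse = "\t"), con, sep = "\n")
  if (nrow(df))
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' Validate the silent-coding constraint of a dictionary
#'
#' Every SDB variant must encode the same peptide: the concatenated barcode,
#' read in the frame given by the dictionary's `sdb_region$offset`, is
#' translated with the standard genetic code and compared with the expected
#' peptide (default `SVEKY`). Stop codons and frame problems are flagged as
#' violations, not raised as errors.
#'
#' @param dict A `liga_dictionary`.
#' @param code Genetic code table, as in [Biostrings::GENETIC_CODE].
#' @param expected_peptide Override for the dictionary's expected peptide.
#' @return `data.frame` with columns `entry_id`, `peptide`, `pass`, `reason`;
#'   attribute `pass` is `TRUE` iff all entries pass (vacuously for an empty
#'   dictionary).
#' @export
validate_silent_coding <- function(dict, code = Biostrings::GENETIC_CODE,
                                   expected_peptide = NULL) {
  expected <- expected_peptide %||% dict$sdb_region$expected_peptide
  offset <- dict$sdb_region$offset
  bc <- dictionary_barcodes(dict)
  n <- length(bc)
  peptide <- character(n); pass <- logical(n); reason <- character(n)
  for (i in seq_len(n)) {
    s <- substr(bc[i], offset + 1L, nchar(bc[i]))
    if (nchar(s) %% 3L != 0L) {
      peptide[i] <- NA_character_; pass[i] <- FALSE
      reason[i] <- "length not a codon multiple after offset"
      next
    }
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aa <- paste(code[codons], collapse = "")
    peptide[i] <- aa
    if (grepl("\\*", aa)) {
      pass[i] <- FALSE; reason[i] <- "stop codon in silent region"
    } else if (!identical(aa, expected)) {
      pass[i] <- FALSE; reason[i] <- sprintf("translates to %s, expected %s", aa, expected)
    } else {
      pass[i] <- TRUE; reason[i] <- ""
    }
  }
  rep <- data.frame(entry_id = names(bc) %||% character(), peptide = peptide,
                    pass = pass, reason = reason, stringsAsFactors = FALSE)
  attr(rep, "pass") <- all(pass)
  attr(rep, "expected_peptide") <- expected
  rep
}

# All synonymous codon spellings of a peptide under the standard genetic code.
synonymous_codons <- function(peptide, code = Biostrings::GENETIC_CODE) {
  aas <- strsplit(peptide, "")[[1]]
  lapply(aas, function(a) names(code)[code == a])
}

# Deterministically enumerate up to `n` distinct silent barcodes encoding
# `peptide`, in an order shuffled by `seed`.
generate_silent_barcodes <- function(n, peptide = "SVEKY", seed = 1L) {
  codon_sets <- synonymous_codons(peptide)
  combos <- expand.grid(codon_sets, stringsAsFactors = FALSE)
  all_bc <- do.call(paste0, combos)
  if (n > length(all_bc))
    stop(sprintf("only %d distinct silent barcodes encode %s; %d requested",
                 length(all_bc), peptide, n))
  with_seed(seed, sample(all_bc))[seq_len(n)]
}

# The six N-glycan structures of the density-series library. Two of the six
# are mixtures (heterogeneous SGP, monosialylated); compositions give the
# dominant species.
liga6x5_structures <- function() {
  list(
    glycan_structure("Man3",   "Man3",
                     c(Hex = 3, HexNAc = 2), "Man"),
    glycan_structure("GN2",    "Man3(GlcNAc)2",
                     c(Hex = 3, HexNAc = 4), "GlcNAc"),
    glycan_structure("A2G2",   "A2G2",
                     c(Hex = 5, HexNAc = 4), "Gal"),
    glycan_structure("A2G2S1", "A2G2S1",
                     c(Hex = 5, HexNAc = 4, Neu5Ac = 1), c("Gal", "Neu5Ac-a2,6")),
    glycan_structure("A2G2S2", "A2G2S2",
                     c(Hex = 5, HexNAc = 4, Neu5Ac = 2), "Neu5Ac-a2,6"),
    glycan_structure("SGPhet", "SGP(het)",
                     c(Hex = 5, HexNAc = 4, Neu5Ac = 2), c("Neu5Ac-a2,6", "Gal"))
  )
}

LIGA_DENSITIES <- c(50L, 150L, 500L, 750L, 1000L)

#' Generate a fixture LiGA dictionary
#'
#' Builds one of three synthetic library designs with barcodes generated as
#' synonymous codon spellings of the expected peptide (so silent-coding
#' validation passes by construction) and pairwise distinct:
#' \describe{
#'   \item{liga6x5}{Six N-glycans at five mean densities (50, 150, 500, 750,
#'     1000 glycans/phage) = 30 glycan clones, plus 10 azidoethanol-capped
#'     invariant clones.}
#'   \item{msdb_man3}{Paucimannose (Man3) at the same five densities, each
#'     density encoded by seven distinct SDBs (35 glycan clones), plus 10
#'     azidoethanol clones.}
#'   \item{invivo}{The 30 liga6x5 glycan clones plus 16 unmodified and 10
#'     azidoethanol "blank" clones (the in vivo invariant baseline).}
#' }
#'
#' @param library One of `"liga6x5"`, `"msdb_man3"`, `"invivo"`.
#' @param seed Integer seed controlling barcode assignment.
#' @return A validated `liga_dictionary`.
#' @export
build_fixture <- function(library = c("liga6x5", "msdb_man3", "invivo"),
                          seed = 1L) {
  library <- match.arg(library)
  peptide <- "SVEKY"
  structures <- liga6x5_structures()

  entry_row <- function(entry_id, lib, class, st, density) {
    data.frame(entry_id = entry_id, library_id = lib, sdb1 = "", sdb2 = "",
               modification_class = class,
               structure_id = if (is.null(st)) "" else st$structure_id,
               cfg_name = if (is.null(st)) "" else st$cfg_name,
               composition = if (is.null(st)) "" else format_composition(st$composition),
               mean_density = density, stringsAsFactors = FALSE)
  }

  rows <- list()
  if (library == "liga6x5" || library == "invivo") {
    lib_id <- if (library == "liga6x5") "L6" else "IV"
    for (st in structures) for (d in LIGA_DENSITIES)
      rows[[length(rows) + 1L]] <-
        entry_row(sprintf("%s_d%d", st$structure_id, d), lib_id, "glycan", st, d)
    if (library == "invivo")
      for (i in seq_len(16))
        rows[[length(rows) + 1L]] <-
          entry_row(sprintf("wt_%02d", i), lib_id, "unmodified", NULL, 0)
    for (i in seq_len(10))
      rows[[length(rows) + 1L]] <-
        entry_row(sprintf("AzEt_%02d", i), lib_id, "azidoethanol", NULL, 0)
  } else {
    man3 <- structures[[1]]
    for (d in LIGA_DENSITIES) for (b in seq_len(7))
      rows[[length(rows) + 1L]] <-
        entry_row(sprintf("Man3_d%d_b%d", d, b), "MS", "glycan", man3, d)
    for (i in seq_len(10))
      rows[[length(rows) + 1L]] <-
        entry_row(sprintf("AzEt_%02d", i), "MS", "azidoethanol", NULL, 0)
  }
  entries <- do.call(rbind, rows)

  bc <- generate_silent_barcodes(nrow(entries), peptide, seed)
  # first three codons (SVE) form SDB1, last two (KY) SDB2
  entries$sdb1 <- substr(bc, 1L, 9L)
  entries$sdb2 <- substr(bc, 10L, 15L)

  liga_dictionary(entries,
                  library_id = entries$library_id[1],
                  sdb_offset = 0L, expected_peptide = peptide,
                  validate = TRUE)
}

#' Convert a display density to percent pVIII occupancy
#'
#' @param density Glycans per virion.
#' @param available pVIII copies available per virion (2700).
#' @param round_to `"exact"` (default) or `"one_sig_fig"`, which reproduces
#'   the conventional rounded figure (1000/2700 -> 40 percent).
#' @return Occupancy in percent.
#' @export
density_to_occupancy <- function(density, available = AVAILABLE_PVIII,
                                 round_to = c("exact", "one_sig_fig")) {
  round_to <- match.arg(round_to)
  if (any(density < 0)) stop("density must be >= 0")
  if (any(density > available)) stop("density exceeds available pVIII copies")
  pct <- 100 * density / available
  if (round_to == "one_sig_fig") signif(pct, 1) else pct
}
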