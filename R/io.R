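#' Read an aligned FASTA file of mitochondrial marker sequences
#'
#' Reads a pre-aligned FASTA file (gaps allowed) and returns one row per
#' record. All sequences must share the aligned length; residues are
#' uppercased and IUPAC ambiguity codes other than `N` are mapped to `N`
#' with a warning, since downstream distances treat them as missing.
#' Records are returned sorted by specimen id so results never depend on
#' file order.
#'
#' @param path Path to a FASTA file.
#' @param marker Marker name, one of `"COI"` or `"16S"`.
#' @return A tibble of class `aligned_sequences` with columns `specimen`,
#'   `marker`, `residues`.
#' @export
read_fasta_alignment <- function(path, marker = c("COI", "16S")) {
  marker <- match.arg(marker)
  assert_that(file.exists(path), paste0("file not found: ", path))
  seqs <- tryCatch(suppressWarnings(ape::read.FASTA(path)),
                   error = function(e) {
    abort(paste0("not a readable FASTA file: ", conditionMessage(e)))
  })
  if (length(seqs) == 0) abort("FASTA file contains no records")
  res <- vapply(as.character(seqs), function(x) paste(x, collapse = ""),
                character(1))
  as_aligned_sequences(tibble::tibble(
    specimen = names(res),
    residues = unname(res)
  ), marker = marker)
}

# Shared constructor/validator: uppercases, maps stray ambiguity codes to N,
# enforces equal aligned lengths and sorts by specimen id.
as_aligned_sequences <- function(df, marker) {
  res <- toupper(df$residues)
  assert_that(all(nzchar(res)), "empty sequence encountered")
  bad <- gsub("[ACGTN-]", "", res)
  if (any(nzchar(bad))) {
    warn(paste0("IUPAC ambiguity codes mapped to N: ",
                paste(unique(strsplit(paste(bad, collapse = ""), "")[[1]]),
                      collapse = " ")))
    res <- vapply(res, function(s) gsub("[^ACGTN-]", "N", s), character(1),
                  USE.NAMES = FALSE)
  }
  lens <- nchar(res)
  if (length(unique(lens)) > 1) {
    abort(paste0("sequences are not aligned: lengths ",
                 paste(sort(unique(lens)), collapse = ", ")))
  }
  assert_that(!anyDuplicated(df$specimen), "duplicate specimen ids in FASTA")
  out <- tibble::tibble(specimen = df$specimen, marker = marker,
                        residues = res)
  out <- out[order(out$specimen), ]
  structure(out, class = c("aligned_sequences", class(tibble::tibble())),
            marker = marker, width = lens[1])
}

#' Write an aligned FASTA file
#'
#' Canonical single-line-per-sequence FASTA; `read_fasta_alignment()` and
#' this writer round-trip bit-identically.
#'
#' @param aln An `aligned_sequences` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  lines <- as.vector(rbind(paste0(">", aln$specimen), aln$residues))
  writeLines(lines, path)
  invisible(path)
}

#' Read a biallelic diploid VCF into a genotype table
#'
#' Consumes GT fields only (any other FORMAT field is ignored), codes
#' genotypes as 0/1/2 alternate-allele dosage, and records missing calls
#' as `NA`. Phasing is ignored: `0|1` and `0/1` both yield dosage 1.
#' Multiallelic records and non-diploid calls are rejected.
#'
#' @param path Path to a VCF (v4.x) file.
#' @return A `genotype_table`: list with `dosage` (individuals x loci
#'   integer matrix, `NA` = missing), `individuals`, `loci`, and `sites`
#'   (tibble with `chrom`, `pos`, `ref`, `alt`).
#' @export
read_genotype_vcf <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no variant records")
  if (any(grepl(",", fix$ALT))) abort("multiallelic sites are not supported")
  if (!any(grepl("GT", v@gt[, "FORMAT"]))) abort("VCF has no GT FORMAT field")
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- gsub("\\|", "/", gt)
  parts <- strsplit(alleles, "/", fixed = TRUE)
  n_alleles <- lengths(parts)
  n_alleles[is.na(gt)] <- 2L
  if (any(n_alleles != 2L)) abort("non-diploid genotype call encountered")
  dose <- vapply(parts, function(a) {
    if (length(a) != 2 || any(a == ".")) return(NA_integer_)
    sum(as.integer(a))
  }, integer(1))
  dosage <- matrix(dose, nrow = nrow(gt), ncol = ncol(gt))
  loci <- paste0(fix$CHROM, ":", fix$POS)
  dosage <- t(dosage)                      # individuals x loci
  ord <- order(colnames(gt))
  dosage <- dosage[ord, , drop = FALSE]
  genotype_table(
    dosage = dosage,
    individuals = colnames(gt)[ord],
    loci = loci,
    sites = tibble::tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                           ref = fix$REF, alt = fix$ALT)
  )
}

genotype_table <- function(dosage, individuals, loci, sites = NULL) {
  assert_that(all(dosage %in% c(0L, 1L, 2L, NA)), "dosages must be 0/1/2/NA")
  assert_that(nrow(dosage) == length(individuals) &&
                ncol(dosage) == length(loci),
              "dosage dimensions inconsistent with id lists")
  dimnames(dosage) <- list(individuals, loci)
  structure(list(dosage = dosage, individuals = individuals, loci = loci,
                 sites = sites),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("<genotype_table> ", length(x$individuals), " individuals x ",
      length(x$loci), " loci; ",
      sum(is.na(x$dosage)), " missing calls\n", sep = "")
  invisible(x)
}

#' Write a genotype table as a minimal VCFv4.2 file
#'
#' Canonical GT-only output; round-trips bit-identically with
#' [read_genotype_vcf()] on files this writer produced.
#'
#' @param g A `genotype_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(g, path) {
  sites <- g$sites
  if (is.null(sites)) {
    cp <- strsplit(g$loci, ":", fixed = TRUE)
    sites <- tibble::tibble(chrom = vapply(cp, `[`, "", 1),
                            pos = as.integer(vapply(cp, `[`, "", 2)),
                            ref = "A", alt = "T")
  }
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  cells <- matrix("./.", nrow = length(g$loci), ncol = length(g$individuals))
  d <- t(g$dosage)
  ok <- !is.na(d)
  cells[ok] <- gt_code[as.character(d[ok])]
  body <- paste(sites$chrom, sites$pos, g$loci, sites$ref, sites$alt,
                ".", "PASS", ".", "GT",
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$individuals), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read raw MALDI-TOF spectra from a directory of CSV tables
#'
#' Each file must be named `<specimen>_<replicate>.csv` and contain two
#' columns `mz,intensity` with a header, m/z ascending. Empty spectra
#' (no rows, or all-zero intensity) are dropped with a warning.
#'
#' @param dir Directory containing the spectra.
#' @return A tibble with columns `specimen`, `replicate`, `trace` (a
#'   list-column of tibbles with `mz`, `intensity`), sorted by specimen
#'   then replicate.
#' @export
read_spectra <- function(dir) {
  assert_that(dir.exists(dir), paste0("directory not found: ", dir))
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  assert_that(length(files) > 0, "no .csv spectra found")
  stem <- sub("\\.csv$", "", basename(files))
  m <- stringr::str_match(stem, "^(.+)_([0-9]+)$")
  assert_that(!anyNA(m[, 1]),
              "spectrum files must be named <specimen>_<replicate>.csv")
  out <- tibble::tibble(
    specimen = m[, 2],
    replicate = as.integer(m[, 3]),
    trace = purrr::map(files, function(f) {
      tr <- readr::read_csv(f, col_types = readr::cols(
        mz = readr::col_double(), intensity = readr::col_double()))
      if (nrow(tr) > 1 && any(diff(tr$mz) <= 0)) {
        abort(paste0("m/z not strictly increasing in ", basename(f)))
      }
      if (any(tr$intensity < 0)) {
        abort(paste0("negative intensities in ", basename(f)))
      }
      tr
    })
  )
  empty <- purrr::map_lgl(out$trace,
                          ~ nrow(.x) == 0 || all(.x$intensity == 0))
  if (any(empty)) {
    warn(paste0(sum(empty), " empty spectra removed: ",
                paste(stem[empty], collapse = ", ")))
    out <- out[!empty, ]
  }
  assert_that(nrow(out) > 0, "all spectra were empty")
  dplyr::arrange(out, .data$specimen, .data$replicate)
}

#' Write spectra to a directory of CSV tables
#'
#' @param spectra A spectra tibble as returned by [read_spectra()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_spectra <- function(spectra, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  purrr::pwalk(spectra[c("specimen", "replicate", "trace")],
               function(specimen, replicate, trace) {
    readr::write_csv(trace, file.path(dir,
      paste0(specimen, "_", replicate, ".csv")))
  })
  invisible(dir)
}

#' Read a specimen metadata table
#'
#' Tab-separated with at least `specimen` and `basin` columns; `station`,
#' `sex`, `mitotype` and other columns pass through. Basin labels are
#' checked against the recognised vocabulary and specimen ids must be
#' unique.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_sample_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  validate_sample_table(tab)
}

validate_sample_table <- function(tab) {
  assert_that(all(c("specimen", "basin") %in% names(tab)),
              "metadata must have 'specimen' and 'basin' columns")
  if (anyDuplicated(tab$specimen)) {
    abort(paste0("duplicate specimen ids in metadata: ",
                 paste(unique(tab$specimen[duplicated(tab$specimen)]),
                       collapse = ", ")))
  }
  bad <- setdiff(unique(tab$basin), BASIN_LEVELS)
  assert_that(length(bad) == 0,
              paste0("unknown basin labels: ", paste(bad, collapse = ", ")))
  tibble::as_tibble(tab)
}

#' Attach specimen metadata to an analysis table
#'
#' Left-joins basin (and any other metadata columns) onto any data frame
#' with a `specimen` column. Specimens absent from the metadata are either
#' an error (default) or dropped with a report.
#'
#' @param x A data frame with a `specimen` column.
#' @param sample_table Metadata tibble (see [read_sample_table()]).
#' @param policy `"error"` or `"drop"` for specimens missing from the table.
#' @return `x` with metadata columns joined; if `policy = "drop"`, the ids
#'   removed are attached as attribute `"dropped"` and reported.
#' @export
join_metadata <- function(x, sample_table, policy = c("error", "drop")) {
  policy <- match.arg(policy)
  sample_table <- validate_sample_table(sample_table)
  assert_that("specimen" %in% names(x), "x must have a 'specimen' column")
  unmatched <- setdiff(unique(x$specimen), sample_table$specimen)
  if (length(unmatched) > 0) {
    if (policy == "error") {
      abort(paste0("specimens missing from metadata: ",
                   paste(unmatched, collapse = ", ")))
    }
    inform(paste0("dropped ", length(unmatched),
                  " specimens missing from metadata: ",
                  paste(unmatched, collapse = ", ")))
    x <- x[!x$specimen %in% unmatched, , drop = FALSE]
  }
  out <- dplyr::left_join(x, sample_table, by = "specimen",
                          suffix = c("", ".meta"))
  attr(out, "dropped") <- unmatched
  out
}
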