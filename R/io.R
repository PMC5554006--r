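#' Read a genotype panel from a TSV matrix or a VCF file
#'
#' The TSV dialect has one row per marker: the first column holds the
#' marker id, the header row the genotype ids, and cells are `0`, `1` or
#' `NA`. For VCF input, haploid (`0`, `1`) and homozygous-diploid
#' (`0/0`, `1|1`, ...) genotype fields are mapped to 0/1; heterozygous
#' calls are set to missing with a warning counting them, and a
#' heterozygote fraction above `max_het` aborts (the panel would violate
#' the inbred-line assumption).
#'
#' @param path File path.
#' @param format `"tsv_matrix"` or `"vcf"` (default guessed from the
#'   extension).
#' @param max_het Maximum tolerated heterozygote fraction for VCF input.
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path, format = NULL, max_het = 0.05) {
  if (is.null(format)) {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv_matrix"
  }
  format <- match.arg(format, c("tsv_matrix", "vcf"))
  if (format == "tsv_matrix") {
    df <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""))
    marker_ids <- as.character(df[[1]])
    dup <- marker_ids[duplicated(marker_ids)]
    if (length(dup)) {
      stop("duplicate marker id in ", path, ": ", dup[1],
           " (line ", which(marker_ids == dup[1])[2] + 1, ")", call. = FALSE)
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    return(genotype_panel(t(m), genotype_ids = colnames(df)[-1],
                          marker_ids = marker_ids))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  marker_ids <- rownames(gt)
  if (anyDuplicated(marker_ids)) {
    stop("duplicate marker id in VCF: ",
         marker_ids[duplicated(marker_ids)][1], call. = FALSE)
  }
  code <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (length(unique(alleles)) > 1) return(-1)  # heterozygote sentinel
    as.numeric(alleles[1])
  }
  calls <- apply(gt, c(1, 2), code)
  n_het <- sum(calls == -1, na.rm = TRUE)
  n_called <- sum(!is.na(calls))
  if (n_called > 0 && n_het / n_called > max_het) {
    stop(sprintf("heterozygote fraction %.1f%% exceeds %.0f%%: not an inbred panel",
                 100 * n_het / n_called, 100 * max_het), call. = FALSE)
  }
  if (n_het > 0) {
    warning(n_het, " heterozygous call(s) set to missing", call. = FALSE)
    calls[calls == -1] <- NA_real_
  }
  genotype_panel(t(calls), genotype_ids = colnames(gt), marker_ids = marker_ids)
}

#' Write a genotype panel as a marker-by-genotype TSV matrix
#'
#' @param panel A [genotype_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  m <- t(panel$calls)
  df <- data.frame(marker_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype panel as a minimal haploid-coded VCF
#'
#' Positions are taken from the genetic map (cM scaled to integer bp-like
#' coordinates); alleles are written as placeholder A/T.
#'
#' @param panel A [genotype_panel()].
#' @param map A [genetic_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(panel, map, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  map <- genetic_map(map)
  map <- map[match(panel$marker_ids, map$marker_id), ]
  gt <- t(panel$calls)
  gt_chr <- ifelse(is.na(gt), ".", as.character(gt))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=growthgwas",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$genotype_ids), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(gt_chr)), function(i) {
    paste(c(map$chromosome[i],
            format(round(map$position_cM[i] * 1e4) + 1, scientific = FALSE),
            panel$marker_ids[i], "A", "T", ".", "PASS", ".", "GT",
            gt_chr[i, ]), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read or write a genetic map TSV (marker_id, chromosome, position_cM)
#'
#' @param path File path.
#' @return [read_genetic_map()]: a [genetic_map()] tibble.
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""))
  genetic_map(df)
}

#' @param map A [genetic_map()] tibble.
#' @rdname read_genetic_map
#' @export
write_genetic_map <- function(map, path) {
  map <- genetic_map(map)
  utils::write.table(map[, c("marker_id", "chromosome", "position_cM")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a long-format phenotype CSV
#'
#' The fixed header is `genotype,experiment,replicate,day,trait,value`.
#'
#' @param path File path.
#' @return [read_phenotypes()]: a phenotype tibble.
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("genotype", "experiment", "replicate", "day", "trait", "value")
  if (!all(req %in% names(df))) {
    stop("phenotype CSV must have header ", paste(req, collapse = ","),
         call. = FALSE)
  }
  dup <- duplicated(df[, req[1:5]])
  if (any(dup)) {
    stop("duplicate (genotype, experiment, replicate, day, trait) record at row ",
         which(dup)[1], call. = FALSE)
  }
  df
}

#' @param records Phenotype tibble.
#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(records, path) {
  req <- c("genotype", "experiment", "replicate", "day", "trait", "value")
  readr::write_csv(dplyr::select(tibble::as_tibble(records),
                                 dplyr::all_of(req)), path)
  invisible(path)
}
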