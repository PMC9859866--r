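#' Read a beta-value matrix from TSV
#'
#' Reads a probes-by-samples matrix of methylation beta values. The file must
#' have a header row of sample identifiers and probe identifiers in the first
#' column. Empty cells become `NA` (missing); all non-missing values must lie
#' in \[0, 1\].
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix with probe ids as rownames and sample ids as
#'   colnames, of class `beta_matrix`.
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (ncol(df) < 2L) stop("beta matrix needs a probe-id column plus >=1 sample column")
  if (anyDuplicated(names(df)[-1L])) stop("duplicate sample ids in beta matrix")
  probes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- probes
  as_beta_matrix(m)
}

#' Validate a numeric matrix as a beta matrix
#'
#' @param m Numeric matrix, probes as rows (rownames = probe ids), samples as
#'   columns (colnames = sample ids). Missing values allowed.
#' @return The validated matrix with class `beta_matrix` prepended.
#' @export
as_beta_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("beta matrix must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("beta matrix needs probe rownames and sample colnames")
  if (anyDuplicated(rownames(m))) stop("duplicate probe ids in beta matrix")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in beta matrix")
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s': %g",
                 rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]],
                 m[bad[1L, 1L, drop = TRUE], bad[1L, 2L, drop = TRUE]]))
  }
  class(m) <- c("beta_matrix", class(m))
  m
}

#' Write a beta matrix to TSV
#'
#' Values are written with six decimal places; `NA` becomes an empty cell.
#'
#' @param beta A `beta_matrix` (or compatible numeric matrix).
#' @param path Output path.
#' @export
write_beta_matrix <- function(beta, path) {
  fmt <- ifelse(is.na(beta), "", sprintf("%.6f", beta))
  dim(fmt) <- dim(beta)
  df <- data.frame(probe_id = rownames(beta), fmt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(beta))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet from CSV
#'
#' Required columns: `sample_id`, `family_id`, `pair_id`, `zygosity` (MZ/DZ),
#' `group` (case/control/reference), `sex` (M/F), `batch`. Additional
#' (clinical) columns are carried through untouched.
#'
#' @param path Path to a CSV file.
#' @return A data.frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  # sex/zygosity columns like "F" must never be parsed as logicals
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  as_sample_sheet(df)
}

#' Validate a data.frame as a sample sheet
#' @param df data.frame with the required columns (see [read_sample_sheet()]).
#' @return `df` with class `sample_sheet` prepended.
#' @export
as_sample_sheet <- function(df) {
  req <- c("sample_id", "family_id", "pair_id", "zygosity", "group", "sex", "batch")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sample sheet missing required column(s): ",
                         paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in sample sheet")
  if (!all(df$zygosity %in% c("MZ", "DZ")))
    stop("zygosity must be 'MZ' or 'DZ'")
  if (!all(df$group %in% c("case", "control", "reference")))
    stop("unknown group label(s): ",
         paste(unique(setdiff(df$group, c("case", "control", "reference"))), collapse = ", "))
  if (!all(df$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  tab <- table(df$pair_id)
  if (any(tab > 2L)) stop("pair_id with more than two members: ",
                          names(tab)[which(tab > 2L)[1L]])
  zyg_per_pair <- tapply(df$zygosity, df$pair_id, function(z) length(unique(z)))
  if (any(zyg_per_pair > 1L))
    stop("pair with discordant zygosity labels: ",
         names(zyg_per_pair)[which(zyg_per_pair > 1L)[1L]])
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' @export
print.sample_sheet <- function(x, ...) {
  cat(sprintf("sample_sheet: %d samples, %d families, %d pairs (%d MZ, %d DZ pairs)\n",
              nrow(x), length(unique(x$family_id)), length(unique(x$pair_id)),
              length(unique(x$pair_id[x$zygosity == "MZ"])),
              length(unique(x$pair_id[x$zygosity == "DZ"]))))
  cat("groups:", paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Write a sample sheet to CSV
#' @param sheet A `sample_sheet`.
#' @param path Output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(as.data.frame(sheet), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CpG manifest from TSV
#'
#' Columns: `probe_id`, `chromosome`, `position` (1-based basepair),
#' `gene_symbols` (semicolon-separated, possibly empty), optional
#' `region_class` (island/promoter/gene body/other). Rows are sorted by
#' (chromosome, position) on read.
#'
#' @param path Path to a TSV file.
#' @return A data.frame of class `cpg_manifest`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA")
  as_cpg_manifest(df)
}

#' Validate a data.frame as a CpG manifest
#' @param df data.frame with columns `probe_id`, `chromosome`, `position` and
#'   optionally `gene_symbols`, `region_class`.
#' @return Sorted, validated manifest of class `cpg_manifest`.
#' @export
as_cpg_manifest <- function(df) {
  req <- c("probe_id", "chromosome", "position")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$probe_id)) stop("duplicate probe ids in manifest")
  if (any(is.na(df$position)) || any(df$position <= 0))
    stop("manifest positions must be positive 1-based coordinates")
  if (is.null(df$gene_symbols)) df$gene_symbols <- ""
  df$gene_symbols[is.na(df$gene_symbols)] <- ""
  ord <- order(df$chromosome, df$position)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("cpg_manifest", "data.frame")
  df
}

#' Write a CpG manifest to TSV
#' @param manifest A `cpg_manifest`.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(as.data.frame(manifest), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Split semicolon-separated gene symbols
#' @param x Character vector of semicolon-separated symbols.
#' @return List of character vectors (empty vector for empty strings).
#' @export
split_gene_symbols <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(g) g[nzchar(g)])
}

#' Write enriched regions to BED
#'
#' Manifest coordinates are 1-based inclusive; BED uses 0-based half-open
#' intervals, so a probe at position 100 spanning one basepair becomes
#' start 99, end 100.
#'
#' @param regions A data.frame of enriched regions (see
#'   [scan_enriched_regions()]), with columns `chromosome`, `start_bp`,
#'   `end_bp`, `direction`, `gene_symbols`, `sample_id`.
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  name <- paste0(regions$direction, ":",
                 ifelse(nzchar(regions$gene_symbols), regions$gene_symbols, "."),
                 ":", regions$sample_id)
  bed <- data.frame(chrom = regions$chromosome,
                    start = regions$start_bp - 1L,
                    end = regions$end_bp,
                    name = name, stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of regions written by [write_regions_bed()]
#' @param path BED path.
#' @return data.frame with `chromosome`, `start_bp` (1-based), `end_bp`,
#'   `direction`, `gene_symbols`, `sample_id`.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(data.frame(chromosome = character(0), start_bp = integer(0),
                      end_bp = integer(0), direction = character(0),
                      gene_symbols = character(0), sample_id = character(0),
                      stringsAsFactors = FALSE))
  df <- utils::read.delim(text = lines, header = FALSE,
                          stringsAsFactors = FALSE)
  parts <- strsplit(df$V4, ":", fixed = TRUE)
  data.frame(chromosome = df$V1,
             start_bp = df$V2 + 1L,
             end_bp = df$V3,
             direction = vapply(parts, `[`, "", 1L),
             gene_symbols = ifelse(vapply(parts, `[`, "", 2L) == ".",
                                   "", vapply(parts, `[`, "", 2L)),
             sample_id = vapply(parts, `[`, "", 3L),
             stringsAsFactors = FALSE)
}
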