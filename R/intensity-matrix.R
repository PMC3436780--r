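#' Isotope-group intensity matrix
#'
#' The central data container of the package: a \code{P x N} matrix of
#' area-under-the-curve (AUC) intensities for \code{P} isotope groups measured
#' across \code{N} LC-MS analyses (samples), together with a missingness mask
#' and per-sample metadata.  An isotope group is the set of chromatographic
#' peaks belonging to one peptide at one charge state and retention time; its
#' AUC intensity is monotone in analyte concentration.  Zeros and blanks in
#' label-free AUC exports are non-detections, so they are carried as missing
#' values rather than as small counts, and are excluded from all downstream
#' likelihood computations.
#'
#' @param values Numeric matrix, rows = isotope groups, columns = samples.
#'   Row names are isotope-group ids, column names are sample ids (generated
#'   when absent).  Non-finite or non-positive entries of a raw matrix are
#'   converted to missing.
#' @param missing Optional logical matrix of the same shape; \code{TRUE}
#'   marks a non-detection.  Merged with the non-finite/non-positive rule.
#' @param raw Logical; \code{TRUE} when \code{values} holds raw AUC counts,
#'   \code{FALSE} after [log_transform()].
#' @param log_base Base of the logarithm applied, \code{NA} for raw data.
#' @param samples Optional tibble/data.frame of per-sample metadata with a
#'   \code{sample_id} column and optionally \code{runblock} (batch label) and
#'   \code{phenotype} (binary outcome).
#'
#' @return An object of class \code{mp_intensity} with fields
#'   \code{values}, \code{missing}, \code{raw}, \code{log_base},
#'   \code{samples}.
#' @seealso [read_intensity_matrix()], [filter_features()],
#'   [log_transform()], [select_modeled_features()]
#' @export
mp_intensity <- function(values, missing = NULL, raw = TRUE,
                         log_base = NA_real_, samples = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("intensity matrix must have at least one row and one column",
         call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("ig_", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s_", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate isotope_group_id in intensity matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample id in intensity matrix", call. = FALSE)
  }
  if (is.null(missing)) {
    missing <- matrix(FALSE, nrow(values), ncol(values))
  }
  missing <- missing | !is.finite(values)
  if (isTRUE(raw)) missing <- missing | (values <= 0 & !missing)
  dimnames(missing) <- dimnames(values)
  values[missing] <- NA_real_
  if (any(!is.finite(values[!missing]))) {
    stop("non-finite observed intensity", call. = FALSE)
  }
  samples <- normalize_sample_metadata(samples, colnames(values))
  structure(
    list(values = values, missing = missing, raw = isTRUE(raw),
         log_base = log_base, samples = samples),
    class = "mp_intensity"
  )
}

normalize_sample_metadata <- function(samples, sample_ids) {
  if (is.null(samples)) {
    return(tibble::tibble(sample_id = sample_ids,
                          runblock = NA_character_,
                          phenotype = NA_integer_))
  }
  samples <- tibble::as_tibble(samples)
  if (!"sample_id" %in% names(samples)) {
    stop("sample metadata needs a sample_id column", call. = FALSE)
  }
  miss <- setdiff(sample_ids, samples$sample_id)
  if (length(miss) > 0) {
    stop("sample metadata is missing ids: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  samples <- samples[match(sample_ids, samples$sample_id), , drop = FALSE]
  if (!"runblock" %in% names(samples)) samples$runblock <- NA_character_
  if (!"phenotype" %in% names(samples)) samples$phenotype <- NA_integer_
  samples
}

#' @export
dim.mp_intensity <- function(x) dim(x$values)

#' @export
dimnames.mp_intensity <- function(x) dimnames(x$values)

#' @export
print.mp_intensity <- function(x, ...) {
  cat(sprintf(
    "<mp_intensity> %d isotope groups x %d samples (%s scale%s), %.1f%% missing\n",
    nrow(x$values), ncol(x$values),
    if (x$raw) "raw AUC" else "log",
    if (!x$raw && is.finite(x$log_base)) sprintf(", base %g", x$log_base) else "",
    100 * mean(x$missing)))
  invisible(x)
}

#' @export
`[.mp_intensity` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  mp_intensity(x$values[i, j, drop = FALSE],
               missing = x$missing[i, j, drop = FALSE],
               raw = x$raw, log_base = x$log_base,
               samples = x$samples[match(colnames(x$values[, j, drop = FALSE]),
                                         x$samples$sample_id), , drop = FALSE])
}

#' @export
as_tibble.mp_intensity <- function(x, ...) {
  tibble::tibble(
    isotope_group_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    intensity = as.vector(x$values),
    missing = as.vector(x$missing)
  )
}

#' Read an isotope-group intensity matrix from a delimited file
#'
#' Expects a header row of sample ids, a first column of isotope-group ids
#' and one row per isotope group (use \code{transpose = TRUE} for exports
#' with samples as rows).  Empty cells, non-numeric cells and values
#' \code{<= 0} are recorded as missing (non-detections).
#'
#' @param path Path to a TSV or CSV file (delimiter sniffed from the
#'   extension; \code{.csv} is comma, anything else tab).
#' @param samples Optional path to a sample-metadata sidecar TSV/CSV with
#'   columns \code{sample_id}, \code{runblock}, \code{phenotype}, or a
#'   data frame with those columns.
#' @param transpose Set \code{TRUE} when rows are samples.
#' @param raw Whether the file holds raw AUC counts (default) or
#'   log-transformed values.
#' @param log_base Log base when \code{raw = FALSE}.
#' @return An [mp_intensity] object.
#' @export
read_intensity_matrix <- function(path, samples = NULL, transpose = FALSE,
                                  raw = TRUE, log_base = NA_real_) {
  tab <- read_delim_auto(path)
  if (nrow(readr::problems(tab)) > 0) {
    stop("malformed table (ragged rows?) in ", path, call. = FALSE)
  }
  if (ncol(tab) < 2L) stop("expected an id column plus data columns", call. = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate isotope_group_id in ", path, call. = FALSE)
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  rownames(vals) <- ids
  if (transpose) vals <- t(vals)
  if (is.character(samples)) samples <- read_delim_auto(samples)
  mp_intensity(vals, raw = raw, log_base = log_base, samples = samples)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE,
                    col_types = readr::cols(.default = readr::col_character()))
}

#' Write an intensity matrix (and optional metadata sidecar) to TSV
#'
#' Values are printed with 17 significant digits so that a write/read
#' round-trip reproduces the matrix bit-exactly; missing cells are written
#' as empty fields.
#'
#' @param x An [mp_intensity] object.
#' @param path Output TSV path.
#' @param samples_path Optional path for the sample-metadata sidecar.
#' @return \code{x}, invisibly.
#' @export
write_intensity_matrix <- function(x, path, samples_path = NULL) {
  stopifnot(inherits(x, "mp_intensity"))
  vals <- x$values
  chr <- matrix(sprintf("%.17g", vals), nrow(vals))
  chr[x$missing] <- ""
  out <- cbind(isotope_group_id = rownames(vals), as.data.frame(chr))
  names(out)[-1] <- colnames(vals)
  readr::write_tsv(tibble::as_tibble(out), path, progress = FALSE)
  if (!is.null(samples_path)) {
    readr::write_tsv(x$samples, samples_path, progress = FALSE)
  }
  invisible(x)
}

#' Read an isotope-group identification table
#'
#' Maps isotope groups to peptide sequences and protein accessions from
#' MS/MS database search results.  Isotope groups absent from the table are
#' treated as unidentified downstream.  Conflicting duplicate records (one
#' isotope group mapped to two proteins or peptides) are an error: ambiguity
#' is not silently resolved.
#'
#' @param path TSV/CSV with columns \code{isotope_group_id},
#'   \code{peptide_sequence}, \code{protein_accession} and optionally
#'   \code{identified} (logical, default \code{TRUE}).
#' @return A tibble with those four columns, one row per isotope group.
#' @export
read_identifications <- function(path) {
  tab <- read_delim_auto(path)
  req <- c("isotope_group_id", "peptide_sequence", "protein_accession")
  if (nrow(tab) == 0 || ncol(tab) == 0) {
    return(tibble::tibble(isotope_group_id = character(),
                          peptide_sequence = character(),
                          protein_accession = character(),
                          identified = logical()))
  }
  if (!all(req %in% names(tab))) {
    stop("identification table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  ids <- tibble::tibble(
    isotope_group_id = as.character(tab$isotope_group_id),
    peptide_sequence = toupper(as.character(tab$peptide_sequence)),
    protein_accession = as.character(tab$protein_accession),
    identified = if ("identified" %in% names(tab)) {
      as.logical(tab$identified)
    } else {
      rep(TRUE, nrow(tab))
    }
  )
  validate_identifications(ids)
}

validate_identifications <- function(ids) {
  ids <- tibble::as_tibble(ids)
  if (!"identified" %in% names(ids)) ids$identified <- TRUE
  dup <- ids[duplicated(ids$isotope_group_id) |
               duplicated(ids$isotope_group_id, fromLast = TRUE), , drop = FALSE]
  if (nrow(dup) > 0) {
    distinct <- dplyr::distinct(dup)
    if (anyDuplicated(distinct$isotope_group_id) > 0) {
      stop("conflicting identification records for isotope group(s): ",
           paste(unique(distinct$isotope_group_id[
             duplicated(distinct$isotope_group_id)]), collapse = ", "),
           call. = FALSE)
    }
    ids <- dplyr::distinct(ids)
  }
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]",
               ids$peptide_sequence[ids$identified & !is.na(ids$peptide_sequence)])
  if (any(bad)) {
    stop("peptide_sequence contains non-standard residue codes", call. = FALSE)
  }
  ids
}

#' Filter isotope groups by detection level
#'
#' Retains the rows whose raw AUC intensity exceeds \code{min_count} in at
#' least a fraction \code{min_fraction} of samples.  The defaults (1000
#' counts, roughly the 10th intensity percentile of a typical serum run, in
#' half the samples) drop features detected too rarely to carry
#' co-expression information.
#'
#' @param x An [mp_intensity] object on the raw count scale.
#' @param min_count Intensity threshold in AUC counts.
#' @param min_fraction Required fraction of samples above threshold.
#' @return The filtered [mp_intensity].
#' @export
filter_features <- function(x, min_count = 1000, min_fraction = 0.5) {
  stopifnot(inherits(x, "mp_intensity"))
  if (!x$raw) {
    stop("filter_features expects raw AUC counts; got log-transformed data",
         call. = FALSE)
  }
  above <- !x$missing & x$values > min_count
  keep <- rowMeans(above) >= min_fraction
  if (!any(keep)) stop("no isotope group passes the detection filter", call. = FALSE)
  x[keep, ]
}

#' Log-transform observed intensities
#'
#' Applies an element-wise logarithm to the observed cells; missing cells
#' stay missing.  Natural log is the default: the model's prior mean of 8
#' for row means matches \code{ln} of typical AUC counts (~3000).
#'
#' @param x An [mp_intensity] object holding raw counts.
#' @param base Log base (default \code{exp(1)}).
#' @return The transformed [mp_intensity] with \code{raw = FALSE}.
#' @export
log_transform <- function(x, base = exp(1)) {
  stopifnot(inherits(x, "mp_intensity"))
  if (!x$raw) stop("data already log-transformed", call. = FALSE)
  obs <- !x$missing
  if (any(x$values[obs] <= 0)) {
    stop("observed non-positive intensity; cannot log-transform", call. = FALSE)
  }
  vals <- x$values
  vals[obs] <- log(vals[obs], base = base)
  mp_intensity(vals, missing = x$missing, raw = FALSE, log_base = base,
               samples = x$samples)
}

#' Select the isotope groups entering the factor model
#'
#' Keeps rows that carry an identification, plus unidentified rows whose
#' mean observed log-intensity exceeds the global mean over all observed
#' cells.  High-abundance unidentified features still contribute
#' co-expression information; dim unidentified features mostly contribute
#' noise.
#'
#' @param x A log-transformed [mp_intensity].
#' @param ids Identification tibble ([read_identifications()]).
#' @return The selected [mp_intensity]; row order is preserved.
#' @export
select_modeled_features <- function(x, ids) {
  stopifnot(inherits(x, "mp_intensity"))
  if (x$raw) stop("select_modeled_features expects log-transformed data", call. = FALSE)
  identified_ids <- ids$isotope_group_id[ids$identified]
  is_id <- rownames(x$values) %in% identified_ids
  obs <- !x$missing
  global_mean <- mean(x$values[obs])
  row_mean <- rowSums(x$values * obs, na.rm = TRUE) / pmax(rowSums(obs), 1L)
  row_mean[rowSums(obs) == 0] <- -Inf
  keep <- is_id | (row_mean > global_mean)
  x[keep, ]
}
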