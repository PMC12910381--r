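# Abundance container: a tibble whose first column is `protein_id` and whose
# remaining columns are one numeric vector per sample. Attributes carry the
# value kind (intensity vs spectral count) and the scale (linear vs log2).

#' Construct an abundance matrix
#'
#' The central quantification container: proteins in rows, samples in columns,
#' held as a tibble whose first column is `protein_id`. Zeros are treated as
#' non-detections and converted to `NA` on construction, so downstream
#' missing-value metrics are well defined. Spectral counts must be integral.
#'
#' @param x A data frame whose first column holds protein accessions and whose
#'   remaining columns are numeric sample values, or a numeric matrix with
#'   row names as accessions.
#' @param value_kind `"intensity"` or `"spectral_count"`.
#' @param scale `"linear"` (raw instrument scale) or `"log2"`.
#' @return A tibble of class `abundance_matrix`.
#' @export
abundance_matrix <- function(x, value_kind = c("intensity", "spectral_count"),
                             scale = c("linear", "log2")) {
  value_kind <- match.arg(value_kind)
  scale <- match.arg(scale)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) stop("matrix input requires row names (accessions)")
    x <- tibble::as_tibble(as.data.frame(x), rownames = "protein_id")
  }
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2L) stop("abundance matrix needs a protein id column and at least one sample column")
  names(x)[1L] <- "protein_id"
  x$protein_id <- as.character(x$protein_id)
  if (anyDuplicated(x$protein_id)) {
    dup <- unique(x$protein_id[duplicated(x$protein_id)])
    stop("duplicate protein ids: ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (anyDuplicated(names(x))) stop("duplicate sample ids in column names")
  for (j in seq(2L, ncol(x))) {
    v <- x[[j]]
    if (!is.numeric(v)) stop("sample column '", names(x)[j], "' is not numeric")
    v[!is.na(v) & v == 0] <- NA_real_
    if (any(v < 0, na.rm = TRUE)) stop("negative value in sample column '", names(x)[j], "'")
    if (value_kind == "spectral_count" && scale == "linear" &&
        any(abs(v - round(v)) > 1e-8, na.rm = TRUE)) {
      stop("spectral counts must be integers (column '", names(x)[j], "')")
    }
    x[[j]] <- as.numeric(v)
  }
  new_abundance_matrix(x, value_kind, scale)
}

new_abundance_matrix <- function(x, value_kind, scale) {
  structure(x,
    class = c("abundance_matrix", class(tibble::tibble())),
    value_kind = value_kind, scale = scale
  )
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf(
    "<abundance_matrix> %d proteins x %d samples (%s, %s scale)\n",
    nrow(x), ncol(x) - 1L, attr(x, "value_kind"), attr(x, "scale")
  ))
  NextMethod()
}

#' Sample ids of an abundance matrix
#' @param am An `abundance_matrix`.
#' @return Character vector of sample ids (column order).
#' @export
am_samples <- function(am) setdiff(names(am), "protein_id")

#' Value kind of an abundance matrix
#' @inheritParams am_samples
#' @return `"intensity"` or `"spectral_count"`.
#' @export
am_value_kind <- function(am) attr(am, "value_kind")

#' Scale of an abundance matrix
#' @inheritParams am_samples
#' @return `"linear"` or `"log2"`.
#' @export
am_scale <- function(am) attr(am, "scale")

#' Extract the numeric value grid
#' @inheritParams am_samples
#' @return Numeric matrix, proteins in rows (row names = accessions).
#' @export
am_values <- function(am) {
  m <- as.matrix(as.data.frame(am)[, am_samples(am), drop = FALSE])
  rownames(m) <- am$protein_id
  storage.mode(m) <- "double"
  m
}

# Rebuild the container around a replacement value grid, keeping attributes
# unless overridden. Used by every transforming step.
am_replace <- function(am, values, scale = am_scale(am), value_kind = am_value_kind(am)) {
  stopifnot(is.matrix(values))
  out <- tibble::tibble(protein_id = rownames(values) %||% character())
  for (s in colnames(values)) out[[s]] <- unname(values[, s])
  new_abundance_matrix(out, value_kind, scale)
}

#' Log2-transform an abundance matrix
#'
#' No-op when the matrix is already on the log2 scale. Values are strictly
#' positive by construction, so the transform is always defined.
#' @inheritParams am_samples
#' @return An `abundance_matrix` on the log2 scale.
#' @export
am_log2 <- function(am) {
  if (am_scale(am) == "log2") return(am)
  am_replace(am, log2(am_values(am)), scale = "log2")
}

#' Write an abundance matrix as a generic delimited matrix
#'
#' First column `protein_id`, one numeric column per sample, tab separated.
#' Missing values are written as empty cells so a round trip through
#' [read_abundance()] reproduces the missingness pattern exactly.
#' @inheritParams am_samples
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_generic_matrix <- function(am, path) {
  readr::write_tsv(tibble::as_tibble(as.data.frame(am)), path, na = "")
  invisible(path)
}
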