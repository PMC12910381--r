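# Reading and validating quantification tables, sample tables and reference
# tables. Three input dialects are supported and autodetected from the header:
#   * generic matrix     — first column protein id, remaining columns numeric
#   * FragPipe-style     — per-sample "<sample> Intensity" / "<sample> Spectral
#                          Count" (and "<sample> MaxLFQ Intensity") columns
#   * DIA-NN-style       — long report with Protein.Group / Run / quantity

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  counts <- c("\t" = lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))),
              ","  = lengths(regmatches(header, gregexpr(",",  header, fixed = TRUE))),
              ";"  = lengths(regmatches(header, gregexpr(";",  header, fixed = TRUE))))
  if (all(counts == 0)) return("\t")
  names(counts)[which.max(counts)]
}

read_delim_chr <- function(path) {
  delim <- sniff_delim(path)
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                    na = character(), progress = FALSE, trim_ws = TRUE)
}

fragpipe_suffixes <- c(" MaxLFQ Intensity", " Intensity", " Spectral Count")
# prefixes that denote summary columns, not samples
fragpipe_summary_prefixes <- c("Combined", "Total", "Summarized")

fragpipe_sample_cols <- function(header, suffix) {
  hits <- header[endsWith(header, suffix)]
  pre <- substr(hits, 1L, nchar(hits) - nchar(suffix))
  keep <- !(pre %in% fragpipe_summary_prefixes) &
    !endsWith(pre, " Unique") & !endsWith(pre, " Total")
  # plain " Intensity" must not swallow "<s> MaxLFQ Intensity"
  if (suffix == " Intensity") keep <- keep & !endsWith(pre, " MaxLFQ")
  stats::setNames(hits[keep], pre[keep])
}

#' Autodetect the dialect of a quantification table
#'
#' Header-signature rules: both `Protein.Group` and `Run` columns present
#' means a DIA-NN-style long report; any column ending `" Spectral Count"`,
#' `" Intensity"` or `" MaxLFQ Intensity"` means a FragPipe-style combined
#' report; otherwise the file is treated as a generic matrix (first column
#' protein id, remaining numeric columns one per sample).
#'
#' For a generic matrix the value kind is inferred from the body: all-integral
#' values are taken to be spectral counts, anything else intensities.
#'
#' @param path Path to a delimited text file with a header row.
#' @return A list of class `format_descriptor` with elements `dialect`
#'   (`"generic_matrix"`, `"fragpipe_combined"` or `"diann_report"`) and
#'   `kinds_present` (subset of `"intensity"`, `"spectral_count"`).
#' @export
detect_format <- function(path) {
  tab <- read_delim_chr(path)
  header <- names(tab)
  if (all(c("Protein.Group", "Run") %in% header)) {
    return(structure(list(dialect = "diann_report", kinds_present = "intensity"),
                     class = "format_descriptor"))
  }
  fp_int <- c(fragpipe_sample_cols(header, " MaxLFQ Intensity"),
              fragpipe_sample_cols(header, " Intensity"))
  fp_sc <- fragpipe_sample_cols(header, " Spectral Count")
  if (length(fp_int) || length(fp_sc)) {
    kinds <- c(if (length(fp_int)) "intensity", if (length(fp_sc)) "spectral_count")
    return(structure(list(dialect = "fragpipe_combined", kinds_present = kinds),
                     class = "format_descriptor"))
  }
  if (ncol(tab) < 2L) {
    stop("cannot detect input format: fewer than two columns; ",
         "closest candidate dialect is generic_matrix ",
         "(protein id column plus numeric sample columns)")
  }
  body <- utils::head(tab[-1L], 50L)
  num <- suppressWarnings(lapply(body, function(v) as.numeric(ifelse(v == "", NA, v))))
  bad <- names(body)[vapply(seq_along(body), function(j) {
    any(is.na(num[[j]]) & body[[j]] != "" & !toupper(body[[j]]) %in% c("NA", "NAN"))
  }, logical(1L))]
  if (length(bad)) {
    stop("cannot detect input format: non-numeric sample column(s) ",
         paste(utils::head(bad, 3L), collapse = ", "),
         "; closest candidate dialect is generic_matrix")
  }
  vals <- unlist(num)
  kind <- if (length(vals) && all(abs(vals - round(vals)) < 1e-8, na.rm = TRUE))
    "spectral_count" else "intensity"
  structure(list(dialect = "generic_matrix", kinds_present = kind),
            class = "format_descriptor")
}

#' @export
print.format_descriptor <- function(x, ...) {
  cat(sprintf("<format_descriptor> dialect=%s kinds=%s\n",
              x$dialect, paste(x$kinds_present, collapse = "+")))
  invisible(x)
}

parse_value_column <- function(chr, colname) {
  v <- suppressWarnings(as.numeric(ifelse(chr == "" | toupper(chr) %in% c("NA", "NAN"),
                                          NA, chr)))
  bad <- which(is.na(v) & chr != "" & !toupper(chr) %in% c("NA", "NAN"))
  if (length(bad)) {
    stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                 chr[bad[1L]], bad[1L], colname))
  }
  v
}

#' Read a quantification table into abundance matrices
#'
#' Returns one [abundance_matrix()] per value kind present (a FragPipe-style
#' report carrying both intensities and spectral counts yields two parallel
#' matrices). Zeros and empty cells become missing values. DIA-NN-style long
#' reports are pivoted to a wide protein-by-run matrix; duplicate protein-run
#' pairs are aggregated by their maximum.
#'
#' @param path Path to the quantification table.
#' @param descriptor A [detect_format()] result; autodetected when omitted.
#' @param diann_quantity_cols Candidate quantity columns for DIA-NN-style
#'   reports, tried in order.
#' @return Named list of `abundance_matrix` objects, one per value kind.
#' @export
read_abundance <- function(path, descriptor = detect_format(path),
                           diann_quantity_cols = c("PG.MaxLFQ", "PG.Quantity", "Intensity")) {
  tab <- read_delim_chr(path)
  switch(descriptor$dialect,
    generic_matrix = {
      mat <- tab
      for (j in seq(2L, ncol(mat))) mat[[j]] <- parse_value_column(mat[[j]], names(mat)[j])
      stats::setNames(list(abundance_matrix(mat, descriptor$kinds_present[1L])),
                      descriptor$kinds_present[1L])
    },
    diann_report = {
      qcol <- diann_quantity_cols[diann_quantity_cols %in% names(tab)][1L]
      if (is.na(qcol)) {
        stop("no quantity column found; looked for: ",
             paste(diann_quantity_cols, collapse = ", "))
      }
      long <- tibble::tibble(
        protein_id = tab$Protein.Group,
        sample_id = tab$Run,
        value = parse_value_column(tab[[qcol]], qcol)
      )
      wide <- long |>
        dplyr::filter(!is.na(.data$value)) |>
        dplyr::group_by(.data$protein_id, .data$sample_id) |>
        dplyr::summarise(value = max(.data$value), .groups = "drop") |>
        tidyr::pivot_wider(names_from = "sample_id", values_from = "value")
      list(intensity = abundance_matrix(wide, "intensity"))
    },
    fragpipe_combined = {
      header <- names(tab)
      id_col <- if ("Protein ID" %in% header) "Protein ID" else header[1L]
      out <- list()
      int_cols <- c(fragpipe_sample_cols(header, " MaxLFQ Intensity"),
                    fragpipe_sample_cols(header, " Intensity"))
      int_cols <- int_cols[!duplicated(names(int_cols))]  # prefer MaxLFQ
      if (length(int_cols)) {
        m <- tibble::tibble(protein_id = tab[[id_col]])
        for (s in names(int_cols)) m[[s]] <- parse_value_column(tab[[int_cols[[s]]]], int_cols[[s]])
        out$intensity <- abundance_matrix(m, "intensity")
      }
      sc_cols <- fragpipe_sample_cols(header, " Spectral Count")
      if (length(sc_cols)) {
        m <- tibble::tibble(protein_id = tab[[id_col]])
        for (s in names(sc_cols)) m[[s]] <- parse_value_column(tab[[sc_cols[[s]]]], sc_cols[[s]])
        out$spectral_count <- abundance_matrix(m, "spectral_count")
      }
      out
    },
    stop("unknown dialect: ", descriptor$dialect)
  )
}

match_col <- function(header, aliases) {
  hit <- which(tolower(header) %in% aliases)
  if (length(hit)) hit[1L] else NA_integer_
}

parse_logical_col <- function(v) {
  lv <- tolower(trimws(v))
  out <- lv %in% c("true", "t", "1", "yes", "y")
  bad <- !lv %in% c("true", "t", "1", "yes", "y", "false", "f", "0", "no", "n", "")
  if (any(bad)) stop("unparseable logical value: '", v[which(bad)[1L]], "'")
  out
}

#' Read a sample table
#'
#' Maps each sample (a column of the quantification matrix) to its sample
#' group. Optional columns: `bait_uniprot` (bait accession for interactomics),
#' `is_control` (control-run flag, default `FALSE`) and `acquisition_order`.
#' Column names are matched case-insensitively with common aliases
#' (`sample`/`sample_id`, `group`/`sample_group`, `bait`/`bait_uniprot`,
#' `control`/`is_control`).
#'
#' @param path Path to a delimited text file.
#' @return Tibble with columns `sample_id`, `sample_group`, `bait_uniprot`,
#'   `is_control`, `acquisition_order`.
#' @export
read_sample_table <- function(path) {
  tab <- read_delim_chr(path)
  header <- names(tab)
  i_sample <- match_col(header, c("sample", "sample_id", "sample id", "sample name"))
  i_group <- match_col(header, c("group", "sample_group", "sample group", "condition"))
  if (is.na(i_sample) || is.na(i_group)) {
    stop("sample table needs a sample column and a group column; found: ",
         paste(header, collapse = ", "))
  }
  i_bait <- match_col(header, c("bait_uniprot", "bait", "bait uniprot"))
  i_ctrl <- match_col(header, c("is_control", "control"))
  i_ord <- match_col(header, c("acquisition_order", "order"))
  out <- tibble::tibble(
    sample_id = as.character(tab[[i_sample]]),
    sample_group = as.character(tab[[i_group]]),
    bait_uniprot = if (!is.na(i_bait)) {
      b <- as.character(tab[[i_bait]]); b[b == ""] <- NA_character_; b
    } else NA_character_,
    is_control = if (!is.na(i_ctrl)) parse_logical_col(tab[[i_ctrl]]) else FALSE,
    acquisition_order = if (!is.na(i_ord)) {
      suppressWarnings(as.integer(tab[[i_ord]]))
    } else NA_integer_
  )
  if (anyDuplicated(out$sample_id)) {
    stop("duplicate sample id(s): ",
         paste(unique(out$sample_id[duplicated(out$sample_id)]), collapse = ", "))
  }
  if (any(is.na(out$sample_group) | out$sample_group == "")) {
    stop("empty sample group for sample(s): ",
         paste(out$sample_id[is.na(out$sample_group) | out$sample_group == ""], collapse = ", "))
  }
  out
}

#' Read a contaminant accession list
#'
#' One accession per line; blank lines and `#` comments are ignored.
#' @param path Path to the list file.
#' @return Character vector of accessions.
#' @export
read_contaminants <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[x != "" & !startsWith(x, "#")]
  unique(x)
}

primary_accession <- function(ids) sub(";.*$", "", ids)

#' Remove common contaminant proteins
#'
#' Drops rows whose primary accession (the token before the first `";"` in a
#' protein-group id) is in the contaminant list. Applied before any other
#' processing; on by default in the pipeline. Idempotent.
#'
#' @param am An [abundance_matrix()].
#' @param contaminants Character vector of contaminant accessions.
#' @param enabled When `FALSE` the matrix is returned unchanged.
#' @return List with `matrix` (filtered `abundance_matrix`) and `removed_ids`.
#' @export
remove_contaminants <- function(am, contaminants, enabled = TRUE) {
  if (!enabled || length(contaminants) == 0L) {
    return(list(matrix = am, removed_ids = character()))
  }
  hit <- primary_accession(am$protein_id) %in% contaminants
  kept <- am[!hit, , drop = FALSE]
  list(matrix = new_abundance_matrix(tibble::as_tibble(as.data.frame(kept)),
                                     am_value_kind(am), am_scale(am)),
       removed_ids = am$protein_id[hit])
}

#' Validate and align a matrix against its sample table
#'
#' Every matrix column must have a sample-table row (error otherwise, listing
#' the offending columns). Sample-table rows without a matching column are
#' dropped with a warning. The matrix columns are reordered to sample-table
#' order so all group-wise computations see a consistent layout.
#'
#' @param am An [abundance_matrix()].
#' @param samples A [read_sample_table()] tibble.
#' @return List with `matrix` (columns in sample-table order) and `samples`
#'   (restricted to matrix columns).
#' @export
align_samples <- function(am, samples) {
  cols <- am_samples(am)
  missing_rows <- setdiff(cols, samples$sample_id)
  if (length(missing_rows)) {
    stop("matrix column(s) absent from sample table: ",
         paste(missing_rows, collapse = ", "))
  }
  extra <- setdiff(samples$sample_id, cols)
  if (length(extra)) {
    warning("sample table row(s) without a matrix column, dropped: ",
            paste(extra, collapse = ", "))
    samples <- samples[samples$sample_id %in% cols, , drop = FALSE]
  }
  ord <- samples$sample_id
  df <- tibble::as_tibble(as.data.frame(am))[, c("protein_id", ord)]
  list(matrix = new_abundance_matrix(df, am_value_kind(am), am_scale(am)),
       samples = samples)
}
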