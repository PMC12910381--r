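# AP-MS scoring and filtering: SAINTexpress file interop, CRAPome-style
# fold-change scores against control runs, high-confidence filtering, known-
# interaction mapping, MS-microscopy localization profiles, local
# hypergeometric enrichment, and network export.

#' Build a spectral-count table for interactomics
#'
#' Combines a spectral-count [abundance_matrix()] with the sample table into
#' the bait-run x prey container used by the interactomics workflow. Missing
#' cells become zero counts (a prey not identified in a run). Every
#' non-control run must carry a bait accession.
#'
#' @param am A spectral-count `abundance_matrix`.
#' @param samples Sample table with `is_control` and (for non-controls)
#'   `bait_uniprot` filled in.
#' @return List of class `sc_table` with `counts` (integer matrix, preys x
#'   runs) and `runs` (tibble `sample_id`, `bait_uniprot`, `is_control`).
#' @export
spectral_counts <- function(am, samples) {
  if (am_value_kind(am) != "spectral_count") {
    stop("interactomics needs spectral counts; got ", am_value_kind(am))
  }
  aligned <- align_samples(am, samples)
  v <- am_values(aligned$matrix)
  v[is.na(v)] <- 0
  runs <- aligned$samples[, c("sample_id", "bait_uniprot", "is_control")]
  no_bait <- !runs$is_control & (is.na(runs$bait_uniprot) | runs$bait_uniprot == "")
  if (any(no_bait)) {
    stop("non-control run(s) without a bait accession: ",
         paste(runs$sample_id[no_bait], collapse = ", "))
  }
  structure(list(counts = v, runs = runs), class = "sc_table")
}

#' @export
print.sc_table <- function(x, ...) {
  cat(sprintf("<sc_table> %d preys x %d runs (%d control)\n",
              nrow(x$counts), ncol(x$counts), sum(x$runs$is_control)))
  invisible(x)
}

#' Write SAINTexpress input files
#'
#' Emits the three tab-separated, headerless files SAINTexpress consumes:
#' `interactions.txt` (run, bait, prey, count; zero-count pairs omitted),
#' `preys.txt` (prey, length, gene name) and `baits.txt` (run, bait, T/C
#' flag; control runs flagged `C`). Control runs with no bait accession are
#' named after their run id. Unknown prey lengths default to 100.
#'
#' @param sc An [spectral_counts()] table.
#' @param prey_lengths Optional named numeric vector of sequence lengths.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_saint_inputs <- function(sc, prey_lengths = NULL, outdir) {
  runs <- sc$runs
  if (!any(runs$is_control)) stop("no control runs designated; SAINT requires controls")
  if (!any(!runs$is_control)) stop("no bait runs present")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  bait_name <- ifelse(runs$is_control,
                      ifelse(is.na(runs$bait_uniprot) | runs$bait_uniprot == "",
                             runs$sample_id, runs$bait_uniprot),
                      runs$bait_uniprot)
  flag <- ifelse(runs$is_control, "C", "T")
  preys <- sort(rownames(sc$counts))

  inter <- character()
  for (i in seq_len(nrow(runs))) {
    cnt <- sc$counts[, runs$sample_id[i]]
    nz <- preys[cnt[preys] > 0]
    inter <- c(inter, sprintf("%s\t%s\t%s\t%d", runs$sample_id[i], bait_name[i],
                              nz, as.integer(cnt[nz])))
  }
  lens <- if (is.null(prey_lengths)) rep(100L, length(preys)) else {
    l <- prey_lengths[preys]
    l[is.na(l)] <- 100L
    as.integer(l)
  }
  paths <- c(
    interactions = file.path(outdir, "interactions.txt"),
    preys = file.path(outdir, "preys.txt"),
    baits = file.path(outdir, "baits.txt")
  )
  writeLines(inter, paths[["interactions"]])
  writeLines(sprintf("%s\t%d\t%s", preys, lens, preys), paths[["preys"]])
  writeLines(sprintf("%s\t%s\t%s", runs$sample_id, bait_name, flag), paths[["baits"]])
  invisible(paths)
}

#' Read a SAINTexpress output list file
#'
#' Parses the tab-separated, headered `list.txt`; the columns `Bait`, `Prey`,
#' `AvgP` and `BFDR` are consumed, extra columns ignored.
#'
#' @param path Path to the list file.
#' @return Tibble with `bait`, `prey`, `avg_p`, `bfdr`.
#' @export
read_saint_output <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"), progress = FALSE)
  need <- c("Bait", "Prey", "AvgP", "BFDR")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("SAINT output is missing column(s): ", paste(miss, collapse = ", "))
  out <- tibble::tibble(
    bait = tab$Bait, prey = tab$Prey,
    avg_p = as.numeric(tab$AvgP), bfdr = as.numeric(tab$BFDR)
  )
  if (any(is.na(out$avg_p)) || any(out$avg_p < 0 | out$avg_p > 1)) {
    stop("AvgP values must be numbers in [0, 1]")
  }
  if (any(is.na(out$bfdr)) || any(out$bfdr < 0 | out$bfdr > 1)) {
    stop("BFDR values must be numbers in [0, 1]")
  }
  out
}

#' CRAPome-style fold-change scores
#'
#' For every bait and every prey detected in at least one of that bait's
#' runs: `fc_a` compares the bait's mean count with the mean over all control
#' runs, `fc_b` with the mean of the `top_k` highest control counts (both
#' with a pseudocount on each side), and `control_frequency` is the fraction
#' of control runs in which the prey was detected.
#'
#' @param sc An [spectral_counts()] table with at least one control run.
#' @param pseudocount Added to both numerator and denominator means.
#' @param top_k Number of highest control counts used for `fc_b`.
#' @return Tibble with `bait`, `prey`, `avg_bait_count`, `fc_a`, `fc_b`,
#'   `control_frequency`, `n_control`.
#' @export
crapome_fold_change <- function(sc, pseudocount = 0.1, top_k = 3L) {
  runs <- sc$runs
  ctrl_ids <- runs$sample_id[runs$is_control]
  if (!length(ctrl_ids)) stop("no control runs designated")
  ctrl <- sc$counts[, ctrl_ids, drop = FALSE]
  ctrl_mean <- rowMeans(ctrl)
  k <- min(top_k, ncol(ctrl))
  ctrl_topk <- apply(ctrl, 1L, function(x) mean(sort(x, decreasing = TRUE)[seq_len(k)]))
  ctrl_freq <- rowMeans(ctrl > 0)
  baits <- unique(runs$bait_uniprot[!runs$is_control])
  purrr::map_dfr(sort(baits), function(b) {
    ids <- runs$sample_id[!runs$is_control & runs$bait_uniprot == b]
    avg <- rowMeans(sc$counts[, ids, drop = FALSE])
    keep <- avg > 0
    tibble::tibble(
      bait = b, prey = rownames(sc$counts)[keep],
      avg_bait_count = unname(avg[keep]),
      fc_a = unname((avg[keep] + pseudocount) / (ctrl_mean[keep] + pseudocount)),
      fc_b = unname((avg[keep] + pseudocount) / (ctrl_topk[keep] + pseudocount)),
      control_frequency = unname(ctrl_freq[keep]),
      n_control = length(ctrl_ids)
    ) |> dplyr::arrange(.data$prey)
  })
}

#' Filter bait-prey records to high confidence
#'
#' A record passes iff `fc_a >= fc_a_min`, `control_frequency <=
#' control_freq_max`, and — when SAINT scores are supplied — `bfdr <=
#' bfdr_max`. Without SAINT scores the filter is fold-change-only. The
#' thresholds used are recorded as the `thresholds` attribute.
#'
#' @param fc A [crapome_fold_change()] tibble.
#' @param saint Optional [read_saint_output()] tibble, joined on bait + prey.
#' @param bfdr_max,fc_a_min,control_freq_max Filter thresholds.
#' @return Tibble of interactome records with `passed` and the score columns.
#' @export
filter_high_confidence <- function(fc, saint = NULL, bfdr_max = 0.05,
                                   fc_a_min = 3, control_freq_max = 0.5) {
  rec <- fc
  if (!is.null(saint)) {
    rec <- dplyr::left_join(rec, saint, by = c("bait", "prey"))
    rec$passed <- !is.na(rec$bfdr) & rec$bfdr <= bfdr_max &
      rec$fc_a >= fc_a_min & rec$control_frequency <= control_freq_max
  } else {
    rec$avg_p <- NA_real_
    rec$bfdr <- NA_real_
    rec$passed <- rec$fc_a >= fc_a_min & rec$control_frequency <= control_freq_max
  }
  attr(rec, "thresholds") <- list(bfdr_max = if (is.null(saint)) NA_real_ else bfdr_max,
                                  fc_a_min = fc_a_min,
                                  control_freq_max = control_freq_max,
                                  saint_used = !is.null(saint))
  rec
}

#' Read a known-interaction reference table
#'
#' Delimited text with two accession columns; pairs are undirected.
#' @param path File path.
#' @return Tibble with `accession_a`, `accession_b`.
#' @export
read_known_interactions <- function(path) {
  tab <- read_delim_chr(path)
  if (ncol(tab) < 2L) stop("known-interaction table needs two accession columns")
  tibble::tibble(accession_a = as.character(tab[[1L]]),
                 accession_b = as.character(tab[[2L]]))
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Map known interactions onto bait-prey records
#'
#' Flags each record whose (bait, prey) pair appears in the reference in
#' either order, and reports per bait the fraction of passed records that are
#' known.
#'
#' @param records A [filter_high_confidence()] tibble.
#' @param reference A [read_known_interactions()] tibble (may be empty).
#' @return List with `records` (plus logical `known`) and `known_fraction`
#'   (tibble `bait`, `n_passed`, `n_known`, `known_fraction`).
#' @export
map_known_interactions <- function(records, reference) {
  keys <- if (nrow(reference)) pair_key(reference$accession_a, reference$accession_b)
          else character()
  records$known <- pair_key(records$bait, records$prey) %in% keys
  frac <- records |>
    dplyr::filter(.data$passed) |>
    dplyr::group_by(bait = .data$bait) |>
    dplyr::summarise(n_passed = dplyr::n(), n_known = sum(.data$known),
                     known_fraction = ifelse(dplyr::n() == 0, 0, mean(.data$known)),
                     .groups = "drop")
  list(records = records, known_fraction = frac)
}

#' Read a localization marker table
#'
#' Delimited text with columns `localization` and `accession` (one marker per
#' row). Localizations may share markers.
#' @param path File path.
#' @return Tibble with `localization`, `accession`.
#' @export
read_marker_table <- function(path) {
  tab <- read_delim_chr(path)
  i_loc <- match_col(names(tab), c("localization", "compartment", "location"))
  i_acc <- match_col(names(tab), c("accession", "uniprot", "marker"))
  if (is.na(i_loc) || is.na(i_acc)) {
    stop("marker table needs localization and accession columns")
  }
  out <- tibble::tibble(localization = as.character(tab[[i_loc]]),
                        accession = as.character(tab[[i_acc]]))
  if (any(out$localization == "")) stop("empty localization name in marker table")
  out
}

#' MS-microscopy localization profile
#'
#' For each bait, the raw score of a localization is the summed average bait
#' count of the passed preys that are markers of that localization; the
#' profile is rescaled so the strongest localization reads 100 (all zeros
#' when no prey overlaps any marker set).
#'
#' @param records A [filter_high_confidence()] tibble (only `passed` records
#'   contribute).
#' @param markers A [read_marker_table()] tibble.
#' @return Tibble with `bait`, `localization`, `score` in \[0, 100\].
#' @export
ms_microscopy_profile <- function(records, markers) {
  locs <- sort(unique(markers$localization))
  if (!length(locs)) stop("marker table has no localizations")
  passed <- dplyr::filter(records, .data$passed)
  purrr::map_dfr(sort(unique(records$bait)), function(b) {
    sub <- passed[passed$bait == b, , drop = FALSE]
    raw <- vapply(locs, function(l) {
      acc <- markers$accession[markers$localization == l]
      sum(sub$avg_bait_count[sub$prey %in% acc])
    }, double(1L))
    score <- if (max(raw) > 0) 100 * raw / max(raw) else raw
    tibble::tibble(bait = b, localization = locs, score = unname(score))
  })
}

#' Read an annotation table (term to accession)
#'
#' Delimited text with columns `term` and `accession`.
#' @param path File path.
#' @return Tibble with `term`, `accession`.
#' @export
read_annotations <- function(path) {
  tab <- read_delim_chr(path)
  i_term <- match_col(names(tab), c("term", "annotation", "category"))
  i_acc <- match_col(names(tab), c("accession", "uniprot", "protein"))
  if (is.na(i_term) || is.na(i_acc)) stop("annotation table needs term and accession columns")
  tibble::tibble(term = as.character(tab[[i_term]]),
                 accession = as.character(tab[[i_acc]]))
}

#' Local hypergeometric enrichment test
#'
#' For each annotation term, the upper-tail hypergeometric probability of
#' observing at least the seen overlap between the prey set and the term's
#' accessions, against a user-supplied background universe; BH-adjusted
#' across terms. This is an offline replacement for web-service enrichment.
#'
#' @param prey_set Character vector of accessions (must lie in `background`).
#' @param annotations A [read_annotations()] tibble.
#' @param background Character vector: the accession universe.
#' @return Tibble with `term`, `n_term`, `n_overlap`, `p`, `p_adj`, ordered
#'   by `p`.
#' @export
enrichment_hypergeometric <- function(prey_set, annotations, background) {
  prey_set <- unique(prey_set)
  background <- unique(background)
  outside <- setdiff(prey_set, background)
  if (length(outside)) {
    stop("prey accession(s) outside the background universe: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  }
  terms <- sort(unique(annotations$term))
  n_bg <- length(background)
  n_draw <- length(prey_set)
  res <- purrr::map_dfr(terms, function(tm) {
    term_set <- intersect(unique(annotations$accession[annotations$term == tm]), background)
    k <- length(intersect(prey_set, term_set))
    p <- stats::phyper(k - 1, length(term_set), n_bg - length(term_set),
                       n_draw, lower.tail = FALSE)
    tibble::tibble(term = tm, n_term = length(term_set), n_overlap = k, p = min(p, 1))
  })
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  dplyr::arrange(res, .data$p, .data$term)
}

#' Export the interaction network as edge and node tables
#'
#' Edges are the passed records (scores carried as attributes), sorted by
#' bait then prey; nodes are annotated `bait`, `prey`, or `both` when a bait
#' accession also occurs as another bait's prey.
#'
#' @param records A [filter_high_confidence()] tibble (optionally with a
#'   `known` column from [map_known_interactions()]).
#' @return List with tibbles `edges` and `nodes`.
#' @export
export_network <- function(records) {
  edges <- records |>
    dplyr::filter(.data$passed) |>
    dplyr::arrange(.data$bait, .data$prey)
  keep <- intersect(c("bait", "prey", "avg_bait_count", "fc_a", "fc_b",
                      "control_frequency", "avg_p", "bfdr", "known"), names(edges))
  edges <- edges[, keep]
  baits <- unique(records$bait)
  preys <- unique(edges$prey)
  ids <- sort(unique(c(baits, preys)))
  nodes <- tibble::tibble(
    id = ids,
    role = dplyr::case_when(ids %in% baits & ids %in% preys ~ "both",
                            ids %in% baits ~ "bait",
                            TRUE ~ "prey")
  )
  list(edges = edges, nodes = nodes)
}
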