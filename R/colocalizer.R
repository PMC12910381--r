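# Colocalization maps from multi-channel confocal z-stacks. Input is a
# multi-page TIFF with a declared page order; the in-memory convention is a
# 4-D array indexed (z, channel, y, x).

#' Read a multi-channel z-stack from a multi-page TIFF
#'
#' Pages are interpreted per `page_order`: `"zc"` means channel varies
#' fastest (z1c1, z1c2, ..., z2c1, ...), `"cz"` means z varies fastest.
#'
#' @param path TIFF path with `n_z * n_channels` pages.
#' @param n_z Number of z-slices.
#' @param n_channels Number of channels (>= 2 for colocalization).
#' @param page_order `"zc"` or `"cz"`.
#' @param channel_names Optional character names for the channel axis.
#' @return Numeric array `(z, channel, y, x)` with nonnegative intensities.
#' @export
read_multichannel_tiff <- function(path, n_z, n_channels, page_order = c("zc", "cz"),
                                   channel_names = NULL) {
  page_order <- match.arg(page_order)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != n_z * n_channels) {
    stop("expected ", n_z * n_channels, " pages (", n_z, " z x ", n_channels,
         " channels), found ", length(pages))
  }
  plane <- function(pg) if (length(dim(pg)) == 3L) pg[, , 1L] else pg
  dims <- dim(plane(pages[[1L]]))[1:2]
  img <- array(0, dim = c(n_z, n_channels, dims[1L], dims[2L]))
  p <- 1L
  if (page_order == "zc") {
    for (z in seq_len(n_z)) for (ch in seq_len(n_channels)) {
      img[z, ch, , ] <- plane(pages[[p]]); p <- p + 1L
    }
  } else {
    for (ch in seq_len(n_channels)) for (z in seq_len(n_z)) {
      img[z, ch, , ] <- plane(pages[[p]]); p <- p + 1L
    }
  }
  if (!is.null(channel_names)) dimnames(img) <- list(NULL, channel_names, NULL, NULL)
  img
}

#' Compute a colocalization map
#'
#' Combines the selected channel planes of one z-slice elementwise by product
#' or sum, optionally compresses the dynamic range with `log(1 + v)`, and
#' min-max rescales the final map to \[0, 1\] (a constant map becomes all
#' zeros). Multiplication highlights pixels bright in every channel; addition
#' shows the union of signals.
#'
#' @param image Array `(z, channel, y, x)` as from [read_multichannel_tiff()].
#' @param z Z-slice index.
#' @param channels Integer (or name) vector of at least two channels.
#' @param mode `"multiply"` or `"add"`.
#' @param scaling `"linear"` or `"log"`.
#' @return Numeric y-by-x matrix with values in \[0, 1\].
#' @export
colocalization_map <- function(image, z, channels, mode = c("multiply", "add"),
                               scaling = c("linear", "log")) {
  mode <- match.arg(mode)
  scaling <- match.arg(scaling)
  if (length(dim(image)) != 4L) stop("image must be a 4-D (z, channel, y, x) array")
  if (length(channels) < 2L) stop("colocalization needs at least 2 channels")
  if (!(is.numeric(z) && z >= 1 && z <= dim(image)[1L])) {
    stop("invalid z-slice index ", z, " (stack has ", dim(image)[1L], ")")
  }
  if (is.character(channels)) {
    channels <- match(channels, dimnames(image)[[2L]])
    if (anyNA(channels)) stop("unknown channel name(s)")
  }
  if (any(channels < 1 | channels > dim(image)[2L])) stop("channel index out of range")
  planes <- lapply(channels, function(ch) image[z, ch, , ])
  combined <- Reduce(if (mode == "multiply") `*` else `+`, planes)
  if (scaling == "log") combined <- log1p(combined)
  rng <- range(combined)
  if (rng[2L] > rng[1L]) (combined - rng[1L]) / (rng[2L] - rng[1L])
  else array(0, dim = dim(combined))
}

#' Write a colocalization map
#'
#' @param map Matrix in \[0, 1\] from [colocalization_map()].
#' @param tiff_path Optional TIFF output path.
#' @param table_path Optional delimited-matrix output path (TSV).
#' @return Invisibly, the paths written.
#' @export
write_colocalization_map <- function(map, tiff_path = NULL, table_path = NULL) {
  if (!is.null(tiff_path)) tiff::writeTIFF(map, tiff_path, bits.per.sample = 16L)
  if (!is.null(table_path)) {
    readr::write_tsv(tibble::as_tibble(as.data.frame(map), .name_repair = "minimal"),
                     table_path, col_names = FALSE)
  }
  invisible(c(tiff = tiff_path, table = table_path))
}
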