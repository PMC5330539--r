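#' Read and write spike rasters as columnar text
#'
#' Lossless two-column text format for \code{\link{SpikeData}}: header
#' lines prefixed \code{#} carry the population sizes and duration,
#' followed by one \code{neuron_index<TAB>time_ms} row per spike with
#' full double precision.  Silent neurons are preserved through the
#' population-size headers.
#'
#' @param x a \code{\link{SpikeData}}.
#' @param path file path.
#' @return \code{writeRaster}: the path, invisibly.  \code{readRaster}:
#'   a \code{SpikeData}; files with unsorted times are normalised with a
#'   warning, malformed lines and missing headers raise errors naming
#'   the offending line or key.
#' @examples
#' r <- generateSurrogate("poisson", n_neurons = 5, rate = 5,
#'                        duration = 1, seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' writeRaster(r, f)
#' identical(spikeTimes(readRaster(f)), spikeTimes(r))
#' @export
writeRaster <- function(x, path) {
  stopifnot(is(x, "SpikeData"))
  nE <- sum(x@label == "E")
  nI <- sum(x@label == "I")
  hdr <- c("# critcap spike raster v1",
           sprintf("# n_E\t%d", nE),
           sprintf("# n_I\t%d", nI),
           sprintf("# duration_ms\t%.17g", x@duration),
           "# columns\tneuron_index\ttime_ms")
  nn <- rep.int(seq_along(x@spikes), lengths(x@spikes))
  tt <- unlist(x@spikes, use.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (length(nn))
    writeLines(sprintf("%d\t%.17g", nn, tt), con)
  invisible(path)
}

#' @rdname writeRaster
#' @export
readRaster <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- lines[hdr]
  getMeta <- function(key) {
    hit <- grep(paste0("^# ", key, "\t"), meta, value = TRUE)
    if (!length(hit)) stop("raster header missing key '", key, "'")
    strsplit(hit[1], "\t")[[1]][2]
  }
  nE <- as.integer(getMeta("n_E"))
  nI <- as.integer(getMeta("n_I"))
  dur <- as.numeric(getMeta("duration_ms"))
  body_idx <- which(!hdr & nzchar(lines))
  nn <- integer(length(body_idx))
  tt <- numeric(length(body_idx))
  for (q in seq_along(body_idx)) {
    parts <- strsplit(lines[body_idx[q]], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2 || is.na(suppressWarnings(as.integer(parts[1]))) ||
        is.na(suppressWarnings(as.numeric(parts[2]))))
      stop("malformed raster line ", body_idx[q], ": '",
           lines[body_idx[q]], "'")
    nn[q] <- as.integer(parts[1])
    tt[q] <- as.numeric(parts[2])
  }
  N <- nE + nI
  if (length(nn) && (min(nn) < 1 || max(nn) > N))
    stop("neuron index outside 1..", N)
  spikes <- unname(split(tt, factor(nn, levels = seq_len(N))))
  unsorted <- vapply(spikes, function(s)
    length(s) > 1 && is.unsorted(s), logical(1))
  if (any(unsorted)) {
    warning("unsorted spike times in ", sum(unsorted),
            " neuron(s); sorting on load")
    spikes[unsorted] <- lapply(spikes[unsorted], sort)
  }
  spikeData(spikes, rep(c("E", "I"), c(nE, nI)), dur,
            params = list(origin = "file", path = path))
}
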