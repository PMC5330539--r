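#' Read and write network parameters as structured text
#'
#' Round-trips a \code{\link{NetworkParams}} object through a Debian
#' control file (DCF): one \code{field: value} line per parameter,
#' mirroring the slot names exactly.  Unknown fields raise an error;
#' missing fields keep their defaults.
#'
#' @param params a \code{\link{NetworkParams}}.
#' @param path file path.
#' @return \code{writeNetworkParams}: the path, invisibly.
#'   \code{readNetworkParams}: a validated \code{NetworkParams}.
#' @examples
#' f <- tempfile(fileext = ".dcf")
#' writeNetworkParams(networkParams(tau_de = 3), f)
#' readNetworkParams(f)@tau_de  # 3
#' @export
writeNetworkParams <- function(params, path) {
  stopifnot(is(params, "NetworkParams"))
  nm <- slotNames("NetworkParams")
  vals <- vapply(nm, function(s) {
    v <- slot(params, s)
    if (is.character(v)) v else format(v, digits = 17)
  }, character(1))
  write.dcf(matrix(vals, nrow = 1, dimnames = list(NULL, nm)), path)
  invisible(path)
}

#' @rdname writeNetworkParams
#' @export
readNetworkParams <- function(path) {
  d <- read.dcf(path)
  if (nrow(d) != 1) stop("expected exactly one parameter record")
  fields <- colnames(d)
  known <- slotNames("NetworkParams")
  bad <- setdiff(fields, known)
  if (length(bad))
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
  args <- lapply(fields, function(f) {
    v <- d[1, f]
    if (f == "model_variant") v
    else if (f %in% c("N", "seed")) as.integer(round(as.numeric(v)))
    else as.numeric(v)
  })
  names(args) <- fields
  do.call(networkParams, args)
}
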