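#' Random network topology
#'
#' Directed Erdos-Renyi connectivity of the E-I network: every ordered pair
#' \eqn{j \to i} with \eqn{j \neq i} is an edge independently with the
#' connection probability \code{C}, so the mean excitatory in-degree is
#' \eqn{C N_E} and the mean inhibitory in-degree \eqn{C N_I}.  The external
#' drive is not represented edge-by-edge: the \code{K_O} independent
#' Poisson sources per neuron are pooled into one Poisson process of rate
#' \eqn{K_O f_{ex}} per neuron during simulation.
#'
#' @slot inE,inI per-neuron integer vectors of incoming excitatory /
#'   inhibitory presynaptic neuron indices.
#' @slot nE,nI population sizes.
#' @seealso \code{\link{buildNetwork}}
#' @exportClass Topology
setClass("Topology",
  slots = c(inE = "list", inI = "list", nE = "integer", nI = "integer")
)

setMethod("show", "Topology", function(object) {
  kE <- mean(lengths(object@inE))
  kI <- mean(lengths(object@inI))
  cat("Topology:", object@nE + object@nI, "neurons (E =", object@nE,
      ", I =", object@nI, ")\n")
  cat("  mean in-degree: excitatory", round(kE, 1), ", inhibitory",
      round(kI, 1), "\n")
})

#' Build the random E-I connectivity
#'
#' Draws the directed adjacency of the network: each ordered neuron pair
#' \eqn{j \to i}, \eqn{j \neq i}, is connected independently with
#' probability \code{params@C}.  Deterministic given \code{seed}.
#'
#' @param params a \code{\link{NetworkParams}} object.
#' @param seed integer seed; defaults to the seed stored in \code{params}.
#' @return a \code{\link{Topology}} object.
#' @examples
#' p <- networkParams(N = 100L, duration = 2)
#' top <- buildNetwork(p, seed = 1)
#' mean(lengths(top@inE)) / nExc(p)  # ~ C
#' @export
buildNetwork <- function(params, seed = params@seed) {
  stopifnot(is(params, "NetworkParams"))
  validObject(params)
  N <- params@N
  nE <- nExc(params)
  .withSeed(seed, {
    inE <- vector("list", N)
    inI <- vector("list", N)
    for (i in seq_len(N)) {
      pre <- which(runif(N) < params@C)
      pre <- pre[pre != i]
      inE[[i]] <- pre[pre <= nE]
      inI[[i]] <- pre[pre > nE]
    }
    new("Topology", inE = inE, inI = inI,
        nE = nE, nI = as.integer(N - nE))
  })
}

# Convert in-adjacency to the out-neighbour CSR arrays (0-based targets)
# consumed by the C++ integrator.
.topologyToCSR <- function(top) {
  N <- top@nE + top@nI
  to <- rep.int(seq_len(N), lengths(top@inE) + lengths(top@inI))
  from <- unlist(lapply(seq_len(N), function(i) c(top@inE[[i]], top@inI[[i]])),
                 use.names = FALSE)
  if (is.null(from)) from <- integer()
  ord <- order(from)
  from <- from[ord]
  to <- to[ord]
  deg <- tabulate(from, nbins = N)
  list(ptr = as.integer(c(0L, cumsum(deg))), idx = as.integer(to - 1L))
}
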