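#' State frequency table for one descriptor
#'
#' @param qual A [qualitative_table()].
#' @param descriptor Descriptor name.
#' @return A tibble: `state` (code), `label`, `count`, `frequency` (%),
#'   one row per observed state in code order; total n as attribute `n`.
#' @examples
#' qt <- simulate_qualitative(list(Seed = c(`1` = 0.4, `2` = 0.6)),
#'                            n_genotypes = 50, seed = 1)
#' state_frequencies(qt, "Seed")
#' @export
state_frequencies <- function(qual, descriptor) {
  stopifnot(inherits(qual, "qualitative_table"))
  i <- match(descriptor, qual$descriptors$name)
  if (is.na(i)) abort(paste0("unknown descriptor: ", descriptor))
  states <- qual$descriptors$states[[i]]
  obs <- qual$observations[[descriptor]]
  obs <- obs[!is.na(obs)]
  if (!length(obs)) abort("domain error: no observations for descriptor")
  counts <- table(factor(obs, levels = states$code))
  out <- tibble(state = states$code, label = states$label,
                count = as.integer(counts))
  out <- out[out$count > 0, ]
  out$frequency <- 100 * out$count / length(obs)
  attr(out, "n") <- length(obs)
  attr(out, "descriptor") <- descriptor
  out
}

#' Normalised Shannon-Weaver diversity index
#'
#' Raw entropy \eqn{H' = -\sum_i p_i \ln p_i} over the observed states
#' (with \eqn{0 \ln 0 := 0}), normalised by \eqn{\ln k} where k is the
#' number of states *defined* for the descriptor (not merely observed), so
#' that 0 means monomorphic and 1 a uniform spread over every defined
#' state.  A single-state descriptor (k = 1) has index 0 by convention.
#'
#' @param counts Integer vector of observed state counts (a
#'   [state_frequencies()] tibble also works).
#' @param k Number of defined states; defaults to `length(counts)`.
#' @return A tibble: `h_raw` (nats), `k`, `h_norm` in `[0, 1]`.
#' @examples
#' shannon_weaver(c(43, 60), k = 2)   # h_norm 0.9803
#' shannon_weaver(103, k = 2)         # monomorphic: 0
#' @export
shannon_weaver <- function(counts, k = NULL) {
  if (is.data.frame(counts)) counts <- counts$count
  counts <- counts[!is.na(counts)]
  if (!length(counts) || sum(counts) < 1) {
    abort("domain error: empty frequency table")
  }
  k <- k %||% length(counts)
  p <- counts / sum(counts)
  p <- p[p > 0]
  h_raw <- -sum(p * log(p)) + 0   # + 0 avoids IEEE negative zero
  h_norm <- if (k <= 1) 0 else h_raw / log(k)
  tibble(h_raw = h_raw, k = as.integer(k), h_norm = h_norm)
}

#' Diversity profile of a qualitative table
#'
#' One row per descriptor with its observed-state count, raw entropy and
#' normalised Shannon-Weaver index; the mean normalised index across
#' descriptors is attached as attribute `mean_h_norm` and reported by
#' [glance.diversity_profile()].
#'
#' @param qual A [qualitative_table()].
#' @return A tibble of class `diversity_profile`: `descriptor`, `k`
#'   (defined states), `n_observed` (observed states), `h_raw`, `h_norm`.
#' @examples
#' qt <- simulate_qualitative(cucumber_descriptor_frequencies(),
#'                            descriptors = cucumber_descriptors(),
#'                            n_genotypes = 103, seed = 1)
#' diversity_profile(qt)
#' @export
diversity_profile <- function(qual) {
  stopifnot(inherits(qual, "qualitative_table"))
  out <- purrr::map_dfr(seq_len(nrow(qual$descriptors)), function(i) {
    d <- qual$descriptors$name[i]
    fr <- state_frequencies(qual, d)
    sw <- shannon_weaver(fr$count, k = qual$descriptors$k[i])
    tibble(descriptor = d, k = sw$k, n_observed = nrow(fr),
           h_raw = sw$h_raw, h_norm = sw$h_norm)
  })
  attr(out, "mean_h_norm") <- mean(out$h_norm)
  class(out) <- c("diversity_profile", class(out))
  out
}

#' @exportS3Method generics::glance
glance.diversity_profile <- function(x, ...) {
  tibble(n_descriptors = nrow(x),
         n_polymorphic = sum(x$h_norm > 0),
         mean_h_norm = attr(x, "mean_h_norm"))
}
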