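#' Modality influence of a coefficient tensor
#'
#' Summarizes which coordinates of one mode (frequency band, temporal lag,
#' channel, ...) drive a fitted multilinear model: the influence of
#' coordinate `i` of the chosen mode is the sum of absolute coefficient
#' values over all other modes (input and output alike), normalized to sum
#' to one so profiles are comparable across models and batches.
#'
#' @param B Numeric coefficient tensor (e.g. from [coef.model_stack()]).
#' @param modality Mode index (into `dim(B)`), or its name if `dimnames`
#'   are set.
#' @param label Optional label stored with the profile (defaults to
#'   `modality`).
#' @return A tibble of class `influence_profile` with columns `modality`,
#'   `index`, `weight` (nonnegative, summing to 1). An all-zero `B` yields
#'   the uniform profile with attribute `degenerate = TRUE`.
#' @examples
#' B <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
#' modality_influence(B, 1)
#' @export
modality_influence <- function(B, modality, label = NULL) {
  B <- as_tensor(B)
  d <- dim(B)
  if (is.character(modality)) {
    nms <- names(dimnames(B))
    modality <- match(modality, nms)
    if (is.na(modality)) stop("unknown modality name")
  }
  if (modality < 1L || modality > length(d)) {
    stop("modality must index a mode of B (1..", length(d), ")")
  }
  w <- apply(abs(B), modality, sum)
  total <- sum(w)
  degenerate <- total == 0
  w <- if (degenerate) rep(1 / d[modality], d[modality]) else w / total
  mode_label <- if (is.null(label)) as.character(modality) else label
  mode_size <- d[modality]
  out <- tibble::tibble(
    modality = mode_label,
    index = seq_len(mode_size),
    weight = as.numeric(w)
  )
  class(out) <- c("influence_profile", class(out))
  attr(out, "degenerate") <- degenerate
  out
}

#' Influence profiles over several modes at once
#'
#' @param B Numeric coefficient tensor.
#' @param modalities Integer vector of mode indices (default: all input
#'   modes given by `n_x_modes`, or all modes).
#' @param labels Optional character labels, one per modality.
#' @param n_x_modes If given and `modalities` is `NULL`, profile the first
#'   `n_x_modes` (input) modes only.
#' @return A tibble with one [modality_influence()] profile per modality,
#'   row-bound.
#' @export
influence_profiles <- function(B, modalities = NULL, labels = NULL,
                               n_x_modes = NULL) {
  d <- dim(as_tensor(B))
  if (is.null(modalities)) {
    modalities <- if (is.null(n_x_modes)) seq_along(d) else seq_len(n_x_modes)
  }
  if (is.null(labels)) labels <- as.character(modalities)
  out <- Map(function(m, l) modality_influence(B, m, label = l),
             modalities, labels)
  do.call(rbind, out)
}

#' Plot an influence profile
#'
#' @param object An `influence_profile` (or the row-bound result of
#'   [influence_profiles()]).
#' @param ... Unused.
#' @return A ggplot object: one panel per modality, weight vs. coordinate.
#' @export
autoplot.influence_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$index, y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~modality, scales = "free_x") +
    ggplot2::labs(x = "coordinate", y = "influence weight")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom ggplot2 .data
NULL
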