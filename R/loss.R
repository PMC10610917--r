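# Deep-supervision training loss: summed binary cross-entropy on every
# side-output saliency map plus the fused map, with per-term weights.

#' Summed binary cross-entropy
#'
#' `e = -sum_(r,c) [ P_G log P_S + (1 - P_G) log(1 - P_S) ]` over all
#' pixels, with the predicted probabilities clipped to
#' `[eps, 1 - eps]` to avoid `log(0)`.
#'
#' @param p_s predicted saliency probability map (values in `[0, 1]`).
#' @param p_g binary ground-truth mask of the same shape.
#' @param eps probability clipping floor.
#' @return Non-negative scalar loss.
#' @export
bce <- function(p_s, p_g, eps = 1e-7) {
  p <- as.numeric(p_s); g <- as.numeric(p_g)
  if (length(p) != length(g)) stop("shape mismatch between P_S and P_G")
  stopifnot(all(g %in% c(0, 1)), all(p >= 0), all(p <= 1))
  p <- pmin(pmax(p, eps), 1 - eps)
  -sum(g * log(p) + (1 - g) * log(1 - p))
}

#' Deep-supervision loss weights
#'
#' @param w_side non-negative weights for the supervised side-output maps
#'   (default: 1 for each of the 10 side maps).
#' @param w_fuse non-negative weight for the final fused map.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(w_side = rep(1, 10), w_fuse = 1) {
  stopifnot(all(w_side >= 0), w_fuse >= 0, any(c(w_side, w_fuse) > 0))
  structure(list(w_side = w_side, w_fuse = w_fuse), class = "loss_weights")
}

#' Total deep-supervision loss
#'
#' `L = sum_m w_side^(m) e_side^(m) + w_fuse e_fuse`, where each `e` is the
#' summed binary cross-entropy of one output map against the ground truth.
#' The supervised side maps are the 10 maps
#' `y01..y04, y05, y10..y40, y50` and the fused term is `y55`.
#'
#' @param outputs a `side_outputs` object from [pfs_forward()], or a plain
#'   named list of maps including `y55`.
#' @param p_g binary ground-truth mask (matrix, or `(H, W, N)` array
#'   matching the maps).
#' @param weights a [loss_weights()].
#' @param eps probability clipping floor.
#' @return Non-negative scalar loss.
#' @export
total_loss <- function(outputs, p_g, weights = loss_weights(), eps = 1e-7) {
  maps <- if (inherits(outputs, "side_outputs")) outputs$maps else outputs
  side_names <- setdiff(names(maps), "y55")
  if (length(weights$w_side) != length(side_names))
    stop(sprintf("expected %d side weights, got %d",
                 length(side_names), length(weights$w_side)))
  total <- weights$w_fuse * bce(maps$y55, p_g, eps)
  for (m in seq_along(side_names))
    total <- total + weights$w_side[m] * bce(maps[[side_names[m]]], p_g, eps)
  total
}

# Autograd version used inside the training loop, computed on the logits
# through the numerically stable fused sigmoid + cross-entropy form (equal
# in value to bce() on the sigmoid maps, up to the eps clipping).
# logit_nodes: named ag nodes of dim (H, W, 1, N); target: matching array.
pfs_loss_nodes <- function(logit_nodes, target, weights = loss_weights()) {
  tgt <- ag_const(target)
  side_names <- setdiff(names(logit_nodes), "y55")
  stopifnot(length(weights$w_side) == length(side_names))
  total <- op_scalar_mul(op_bce_logits_sum(logit_nodes$y55, tgt),
                         weights$w_fuse)
  for (m in seq_along(side_names)) {
    if (weights$w_side[m] == 0) next
    term <- op_scalar_mul(op_bce_logits_sum(logit_nodes[[side_names[m]]],
                                            tgt),
                          weights$w_side[m])
    total <- op_add(total, term)
  }
  total
}
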