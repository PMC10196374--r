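# Loss functions: conditional / unconditional adversarial terms (binary
# cross-entropy on discriminator confidence maps), L1 generation loss,
# L1 refinement loss, and the weighted total.

#' Loss weights
#'
#' Weights of the L1 generation term (`lambda1`) and the refinement term
#' (`lambda2`) in the total generator objective. Defaults follow the
#' experimentally chosen values lambda1 = 100, lambda2 = 10.
#'
#' @param lambda1 weight of the paired L1 generation loss.
#' @param lambda2 weight of the paired L1 refinement loss.
#' @return object of class `loss_weights`.
#' @export
loss_weights <- function(lambda1 = 100, lambda2 = 10) {
  if (lambda1 < 0 || lambda2 < 0)
    stop("loss weights must be non-negative", call. = FALSE)
  structure(list(lambda1 = lambda1, lambda2 = lambda2),
            class = "loss_weights")
}

.bce_eps <- 1e-12

check_unit_interval <- function(x, name) {
  if (any(x < 0) || any(x > 1))
    stop(name, " must contain probabilities in (0, 1)", call. = FALSE)
  invisible(x)
}

safe_log <- function(x) log(pmax(x, .bce_eps))

#' Adversarial loss terms from discriminator confidence maps
#'
#' The discriminator loss is the mean binary cross-entropy pushing real maps
#' toward 1 and fake maps toward 0, averaged over map elements and halved so
#' that the uninformative fixed point (all outputs 0.5) scores exactly
#' `log(2)` per element. The generator term defaults to the non-saturating
#' surrogate `-log D(fake)`; `saturating = TRUE` restores the literal minimax
#' form `log(1 - D(fake))` (negated so lower is better for the generator).
#'
#' `conditional_adversarial_terms()` is used with the pair discriminator D1
#' (which sees the corrupted input concatenated with a candidate);
#' `unconditional_adversarial_terms()` with the single-image discriminator
#' D2. The arithmetic is identical; the two names keep call sites aligned
#' with the two objectives.
#'
#' @param d_real_map,d_fake_map discriminator confidence maps in (0, 1).
#' @param saturating use the saturating minimax generator term.
#' @return `list(d_loss, g_adv_loss)`, scalars in nats.
#' @export
conditional_adversarial_terms <- function(d_real_map, d_fake_map,
                                          saturating = FALSE) {
  check_unit_interval(d_real_map, "d_real_map")
  check_unit_interval(d_fake_map, "d_fake_map")
  d_loss <- 0.5 * (mean(-safe_log(d_real_map)) +
                   mean(-safe_log(1 - d_fake_map)))
  g_adv <- if (saturating) mean(safe_log(1 - d_fake_map))
           else mean(-safe_log(d_fake_map))
  list(d_loss = d_loss, g_adv_loss = g_adv)
}

#' @rdname conditional_adversarial_terms
#' @export
unconditional_adversarial_terms <- function(d_real_map, d_fake_map,
                                            saturating = FALSE) {
  res <- conditional_adversarial_terms(d_real_map, d_fake_map, saturating)
  list(d_loss = res$d_loss, g_adv_loss_u = res$g_adv_loss)
}

#' L1 generation loss
#'
#' Mean absolute difference between a generated image and its artifact-free
#' reference, averaged over pixels and channels on the model `[-1, 1]` scale.
#' Using means rather than sums keeps the loss weights scale-free across
#' image sizes.
#'
#' @param generated,reference arrays of identical shape.
#' @return non-negative scalar.
#' @export
l1_generation_loss <- function(generated, reference) {
  check_same_shape(generated, reference)
  mean(abs(generated - reference))
}

#' L1 refinement loss
#'
#' The refinement module is constrained by the same L1 distance as the
#' generator, evaluated on its refined output. Defined on paired samples
#' only.
#'
#' @param refined,reference arrays of identical shape.
#' @return non-negative scalar.
#' @export
refinement_loss <- function(refined, reference) {
  l1_generation_loss(refined, reference)
}

#' Total generator objective
#'
#' `g_adv_ca + lambda1 * L1 + g_adv_uca + lambda2 * L_ref`. Components that
#' do not apply in the current step or model variant (e.g. the unpaired
#' adversarial term in a paired-only variant) enter as `NA` and are treated
#' as absent (zero contribution).
#'
#' @param components a [loss_report()] or named list with fields `l_ca`
#'   (generator side), `l_l1`, `l_uca`, `l_ref`.
#' @param w a [loss_weights()].
#' @return scalar total loss.
#' @export
total_generator_loss <- function(components, w = loss_weights()) {
  stopifnot(inherits(w, "loss_weights"))
  val <- function(x) if (is.null(x) || is.na(x)) 0 else x
  val(components$l_ca) + w$lambda1 * val(components$l_l1) +
    val(components$l_uca) + w$lambda2 * val(components$l_ref)
}

#' Named loss components for one training step
#'
#' @param l_ca generator-side conditional adversarial term.
#' @param l_l1 L1 generation loss.
#' @param l_uca generator-side unconditional adversarial term.
#' @param l_ref refinement loss.
#' @param d1_loss,d2_loss discriminator losses.
#' @param total weighted generator total.
#' @return a one-row [tibble::tibble()] of class `loss_report`; absent
#'   components are `NA`.
#' @export
loss_report <- function(l_ca = NA_real_, l_l1 = NA_real_, l_uca = NA_real_,
                        l_ref = NA_real_, d1_loss = NA_real_,
                        d2_loss = NA_real_, total = NA_real_) {
  out <- tibble::tibble(l_ca = l_ca, l_l1 = l_l1, l_uca = l_uca,
                        l_ref = l_ref, d1_loss = d1_loss, d2_loss = d2_loss,
                        total = total)
  class(out) <- c("loss_report", class(out))
  out
}
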