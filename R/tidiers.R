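#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the training history of a detector
#'
#' @param x A trained `detector_model`.
#' @param ... Unused.
#' @return Tibble of per-epoch records (`epoch`, `train_loss`,
#'   `validation_mre`, `lr`).
#' @export
tidy.detector_model <- function(x, ...) {
  if (is.null(x$records))
    abort("This detector has not been trained; no records to tidy.")
  x$records
}

#' One-row summary of a detector fit
#'
#' @param x A `detector_model`.
#' @param ... Unused.
#' @return Tibble with parameter count, configured width, epochs trained,
#'   final training loss and final validation MRE.
#' @export
glance.detector_model <- function(x, ...) {
  r <- x$records
  tibble(
    n_parameters = n_params(x$params),
    backbone_width = x$config$backbone_width,
    epochs_trained = if (is.null(r)) 0L else max(r$epoch),
    final_train_loss = if (is.null(r)) NA_real_ else r$train_loss[nrow(r)],
    final_validation_mre = if (is.null(r)) NA_real_ else
      r$validation_mre[nrow(r)])
}

#' Tidy an agreement report
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return One-row tibble with MAD, AD fractions, bias and limits of
#'   agreement.
#' @export
tidy.agreement_report <- function(x, ...) tidy_agreement_row(x)

#' @rdname tidy.agreement_report
#' @export
glance.agreement_report <- function(x, ...) tidy_agreement_row(x)
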