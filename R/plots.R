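# Diagnostic plots (ggplot2, optional).

#' Plot a training history
#'
#' Loss components and validation PSNR per epoch.
#'
#' @param history the `history` tibble returned by [fit()].
#' @return a ggplot object.
#' @export
plot_history <- function(history) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_history requires the 'ggplot2' package", call. = FALSE)
  long <- do.call(rbind, lapply(
    c("l_l1", "d1_loss", "d2_loss", "val_psnr"),
    function(nm) {
      if (all(is.na(history[[nm]]))) return(NULL)
      tibble::tibble(epoch = history$epoch, metric = nm,
                     value = history[[nm]])
    }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training losses and validation PSNR")
}
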