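#' Plot a per-subject evaluation report
#'
#' Bar panels of authentication accuracy, false acceptance rate and key
#' length per subject.
#'
#' @param object An `nk_evaluation` tibble from [evaluate_enrollment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nk_evaluation <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select("subject_id", "accuracy", "far", "key_length") |>
    tidyr::pivot_longer(-"subject_id", names_to = "metric") |>
    dplyr::mutate(metric = factor(.data$metric,
                                  levels = c("accuracy", "far", "key_length"),
                                  labels = c("authentication accuracy",
                                             "false acceptance rate",
                                             "key length (bits)")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$subject_id, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot enrollment key lengths
#'
#' @param object An `nk_enrollment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nk_enrollment <- function(object, ...) {
  tt <- tidy(object)
  ggplot2::ggplot(tt, ggplot2::aes(x = .data$subject_id, y = .data$key_length)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "key length (bits)") +
    ggplot2::theme_minimal()
}

#' Plot a parameter sweep
#'
#' Line plot of the swept metrics against the swept parameter
#' (see [sweep_alpha()] and [sweep_gamma()]).
#'
#' @param object An `nk_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nk_sweep <- function(object, ...) {
  par_name <- attr(object, "parameter") %||% names(object)[1]
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(-dplyr::all_of(par_name), names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[par_name]], y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = par_name, y = NULL) +
    ggplot2::theme_minimal()
}
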