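#' Tidy a healing run
#'
#' @param x an `oh_healing` run.
#' @param type `"daily"` for the per-day summary (one row per day),
#'   `"fields"` for the full per-day per-element table.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.oh_healing <- function(x, type = c("daily", "fields"), ...) {
  type <- match.arg(type)
  if (type == "daily") return(x$daily)
  dplyr::bind_rows(purrr::imap(x$fields, function(f, d) {
    dplyr::mutate(f, day = d, .before = 1)
  }))
}

#' One-row summary of a healing run
#'
#' @param x an `oh_healing` run.
#' @param ... unused.
#' @return One-row tibble: days, diffusivity, final BIC/BA (with
#'   mature/immature splits) and final mean callus modulus.
#' @export
glance.oh_healing <- function(x, ...) {
  last <- x$fields[[x$days]]
  mor <- morphometry(last, x$roi, x$mesh)
  dplyr::bind_cols(
    tibble::tibble(days = x$days, D = x$D,
                   mean_modulus = x$daily$mean_modulus[x$days],
                   mean_S = x$daily$mean_S[x$days]),
    mor)
}
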