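#' Normalized left-right asymmetry index
#'
#' AI = 2 (L - R) / (L + R). Positive values denote leftward asymmetry
#' (left larger), negative values rightward. The index is antisymmetric in
#' its arguments and invariant to common positive scaling.
#'
#' @param left_fd,right_fd Numeric vectors (recycled to common length) of
#'   paired left/right measurements with positive sums.
#' @return Numeric vector of asymmetry indices in (-2, 2).
#' @export
#' @examples
#' asymmetry_index(2.43, 2.42)
asymmetry_index <- function(left_fd, right_fd) {
  s <- left_fd + right_fd
  bad <- !is.na(s) & s <= 0
  if (any(bad))
    cfd_stop("asymmetry index undefined: left + right must be positive",
             "argument_error")
  2 * (left_fd - right_fd) / s
}

#' Per-subject asymmetry indices for the five region pairs
#'
#' @param table A subject FD table (data frame with the `fd_*` columns).
#' @return Data frame with columns `ai_hemisphere`, `ai_frontal`,
#'   `ai_temporal`, `ai_parietal`, `ai_occipital` (NA where either side is
#'   missing).
#' @export
asymmetry_table <- function(table) {
  out <- lapply(REGION_PAIRS, function(pr) {
    L <- table[[pr[1]]]; R <- table[[pr[2]]]
    ifelse(is.na(L) | is.na(R), NA_real_, 2 * (L - R) / (L + R))
  })
  as.data.frame(setNames(out, paste0("ai_", names(REGION_PAIRS))))
}
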