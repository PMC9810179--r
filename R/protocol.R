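#' The nine-trial rotation protocol
#'
#' The default task protocol: nine chair-rotation sequences of increasing
#' complexity. Angles are signed degrees, positive = clockwise, negative =
#' anticlockwise; trials with several angles are executed as consecutive
#' rotations before the participant points back at the remembered
#' reference.
#'
#' @return A tibble with one row per rotation step and columns
#'   `trial_id` (integer 1-9), `step` (integer, order within the trial) and
#'   `rotation_deg` (signed degrees).
#' @export
#' @examples
#' vrt_protocol()
#' vrt_protocol() |> net_rotation()
vrt_protocol <- function() {
  rot <- list(
    `1` = 90,
    `2` = c(90, -210),
    `3` = 120,
    `4` = 300,
    `5` = c(145, -230),
    `6` = c(230, -130),
    `7` = c(-225, 290, 60),
    `8` = c(-290, 265, -70),
    `9` = c(-200, 310, -190)
  )
  tibble::tibble(
    trial_id = rep(1:9, lengths(rot)),
    step = unlist(lapply(lengths(rot), seq_len), use.names = FALSE),
    rotation_deg = unlist(rot, use.names = FALSE)
  )
}

validate_protocol <- function(protocol) {
  stopifnot(
    is.data.frame(protocol),
    all(c("trial_id", "step", "rotation_deg") %in% names(protocol)),
    nrow(protocol) > 0,
    all(protocol$rotation_deg != 0),
    all(protocol$trial_id == as.integer(protocol$trial_id))
  )
  invisible(protocol)
}

#' Net (algebraic) rotation per trial
#'
#' Sums each trial's signed rotations without wrapping; this is where the
#' chair leaves the participant's body pointing, relative to where they
#' started, before the pointing response.
#'
#' @param protocol A protocol tibble as returned by [vrt_protocol()].
#' @return A tibble with columns `trial_id` and `net_rotation_deg`.
#' @export
net_rotation <- function(protocol = vrt_protocol()) {
  validate_protocol(protocol)
  protocol |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::summarise(net_rotation_deg = sum(.data$rotation_deg), .groups = "drop")
}

#' Body-relative turn that points back at the reference
#'
#' Given the body's current compass bearing, the signed minimal turn that
#' brings it onto the reference bearing. A perfect (error-free) responder
#' executes exactly this turn.
#'
#' @param body_heading_deg Current body bearing, degrees in `[0, 360)`.
#' @param reference_heading_deg Reference bearing, degrees in `[0, 360)`.
#' @return Signed degrees in `(-180, 180]`.
#' @export
#' @examples
#' required_turn(350, 10) # 20: across north, the short way
required_turn <- function(body_heading_deg, reference_heading_deg) {
  stopifnot(
    all(body_heading_deg >= 0 & body_heading_deg < 360),
    all(reference_heading_deg >= 0 & reference_heading_deg < 360)
  )
  wrap_signed(reference_heading_deg - body_heading_deg)
}

#' Read or write a protocol as JSON
#'
#' Custom protocols are interchanged as a JSON array of
#' `{"trial_id": i, "rotations": [...]}` objects.
#'
#' @param path File path.
#' @param protocol Protocol tibble (for writing).
#' @return `read_protocol()` returns a protocol tibble;
#'   `write_protocol()` returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  rot <- doc$rotations
  if (!is.list(rot)) rot <- as.list(rot)
  out <- tibble::tibble(
    trial_id = rep(as.integer(doc$trial_id), lengths(rot)),
    step = unlist(lapply(lengths(rot), seq_len), use.names = FALSE),
    rotation_deg = as.numeric(unlist(rot, use.names = FALSE))
  )
  validate_protocol(out)
  out
}

#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, path) {
  validate_protocol(protocol)
  doc <- protocol |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::summarise(rotations = list(.data$rotation_deg), .groups = "drop")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
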