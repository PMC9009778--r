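#' The 18-body-part movement set
#'
#' Returns the ordered set of body parts used by the whole-body motor task,
#' in cortical homunculus order (1 = toes, 18 = tongue), together with the
#' run-part each body part is cued in. The task is split over two screen
#' images: part 1 cues the torso, arm and hand (abdomen through thumb),
#' part 2 cues the leg and face (toes, ankle, knee and the six face parts).
#'
#' @param labels Character vector of body-part names, homunculus order.
#' @param run_part Integer vector, same length as `labels`, assigning each
#'   part to one of the run-parts.
#' @return A data.frame of class `body_part_set` with columns `index`,
#'   `label`, `run_part`.
#' @examples
#' body_parts()
#' @export
body_parts <- function(labels = c("toes", "ankle", "knee", "abdomen",
                                  "shoulder", "elbow", "wrist",
                                  "little_finger", "ring_finger",
                                  "middle_finger", "index_finger", "thumb",
                                  "forehead", "eyelid", "nose", "lips",
                                  "jaw", "tongue"),
                       run_part = c(2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L, 1L,
                                    1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L)) {
  if (anyDuplicated(labels)) stop("body-part labels must be unique")
  if (length(labels) != length(run_part))
    stop("`labels` and `run_part` must have the same length")
  run_part <- as.integer(run_part)
  if (anyNA(run_part)) stop("`run_part` must be integer-valued")
  out <- data.frame(index = seq_along(labels), label = labels,
                    run_part = run_part, stringsAsFactors = FALSE)
  class(out) <- c("body_part_set", "data.frame")
  out
}
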