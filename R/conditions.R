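#' The 18 experimental conditions
#'
#' The analysis is indexed throughout by the factorial crossing of the nine
#' cue conjunctions (3 orientations x 3 spatial frequencies) with the two
#' single-feature search tasks (`SF`, `ORIENTATION`).  Condition order is
#' fixed: all SF-task conditions first, then all ORIENTATION-task conditions,
#' cue id ascending within task; every RDM, design matrix and beta image in
#' the package uses this ordering, which makes RDM vectorization reproducible.
#'
#' @return A data frame with 18 rows and columns `label`, `task`, `cue_id`,
#'   `orientation` (degrees), `sf` (cycles/degree).
#' @examples
#' cs <- condition_set()
#' nrow(cs)   # 18
#' @export
condition_set <- function() {
  cues <- cue_set()
  tasks <- c("SF", "ORIENTATION")
  out <- do.call(rbind, lapply(tasks, function(task) {
    data.frame(
      label = sprintf("%s_cue%d", task, seq_len(9)),
      task = task,
      cue_id = seq_len(9),
      orientation = vapply(cues, `[[`, numeric(1), "orientation"),
      sf = vapply(cues, `[[`, numeric(1), "spatial_frequency"),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
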