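#' The moral dilemma battery design
#'
#' The battery crosses 6 dilemma stories with a norm manipulation
#' (proscriptive: the norm forbids the focal action; prescriptive: the norm
#' mandates it) and a consequence manipulation (benefits of acting greater or
#' smaller than its costs), giving 24 scenarios per participant and four
#' analysis conditions of 6 trials each.
#'
#' @return A data frame with 24 rows and columns `dilemma_id`, `norm_type`,
#'   `consequence_dir`, one per scenario.
#' @examples
#' nrow(battery_design())  # 24
#' @export
battery_design <- function() {
  grid <- expand.grid(
    dilemma_id = DILEMMA_IDS,
    norm_type = NORM_TYPES,
    consequence_dir = CONSEQUENCE_DIRS,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid[order(grid$dilemma_id, grid$norm_type, grid$consequence_dir), ,
       drop = FALSE][, c("dilemma_id", "norm_type", "consequence_dir")] ->
    grid
  rownames(grid) <- NULL
  grid
}

DILEMMA_IDS <- c("abduction", "transplant", "torture", "assisted_suicide",
                 "immune", "vaccine")
NORM_TYPES <- c("proscriptive", "prescriptive")
CONSEQUENCE_DIRS <- c("benefits_greater", "benefits_smaller")

# canonical condition ordering used throughout: proscriptive/greater,
# proscriptive/smaller, prescriptive/greater, prescriptive/smaller
condition_grid <- function() {
  data.frame(
    norm_type = rep(NORM_TYPES, each = 2L),
    consequence_dir = rep(CONSEQUENCE_DIRS, times = 2L),
    stringsAsFactors = FALSE
  )
}

condition_key <- function(norm_type, consequence_dir) {
  paste(norm_type, consequence_dir, sep = ".")
}
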