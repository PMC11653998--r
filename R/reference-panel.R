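# Reference panel of modified Gompertz parameter triples used as generating
# ground truth for synthetic validation of the fitting pipeline.

#' Reference panel of kinetic parameter sets
#'
#' A curated panel of modified Gompertz parameter triples (Hmax mL/L,
#' Rmax mL/L/h, lag h) representative of batch dark-fermentation biohydrogen
#' experiments: a five-isolate screen on 6% glucose medium, a screen of fruit
#' and vegetable peel waste (FVPW) substrates with uninoculated negative
#' controls, and a set of watermelon-peel : melon-peel (WMP:MP) mixture
#' ratios. Mixture rows additionally carry the initial reducing sugar
#' concentration `s_initial` (g/L). The panel serves as generating ground
#' truth for [generate_screening_panel()] round-trip validation.
#'
#' @return A data.frame with columns `panel`, `condition`, `h_max`, `r_max`,
#'   `lag`, `s_initial`.
#' @export
#' @examples
#' head(reference_panel())
reference_panel <- function() {
  rows <- rbind(
    # isolate screen, 6% glucose RCM
    data.frame(panel = "isolate_screen",
               condition = c("NE91", "NE92", "NE93", "NE94", "NE95"),
               h_max = c(830.00, 1342.00, 1269.67, 1508.33, 1617.67),
               r_max = c(210.00, 714.48, 692.62, 774.41, 870.77),
               lag = c(32.88, 28.41, 28.50, 28.39, 28.37),
               s_initial = c(60, 60, 60, 60, 60)),
    # FVPW substrate screen: inoculated (NE95) and negative-control (NC) rows
    data.frame(panel = "fvpw_screen",
               condition = c("banana_NC", "banana_NE95", "melon_NC",
                             "melon_NE95", "orange_NC", "orange_NE95",
                             "potato_NC", "potato_NE95", "watermelon_NC",
                             "watermelon_NE95"),
               h_max = c(70.33, 252.33, 76.33, 736.33, 94.00, 600.00,
                         39.33, 516.33, 59.33, 900.67),
               r_max = c(26.41, 84.91, 24.20, 193.89, 31.57, 120.81,
                         12.21, 116.38, 19.65, 227.63),
               lag = c(27.93, 40.23, 28.33, 34.21, 22.32, 39.23,
                       22.12, 39.56, 22.11, 33.97),
               s_initial = NA_real_),
    # WMP:MP mixture-ratio series
    data.frame(panel = "wmp_mp_mixtures",
               condition = c("WMP", "MP", "1:1", "1:2", "1:3", "2:1", "3:1"),
               h_max = c(900.67, 736.33, 991.00, 483.67, 785.33, 596.67, 858.00),
               r_max = c(227.63, 193.89, 236.31, 125.31, 214.29, 127.65, 219.62),
               lag = c(33.97, 34.21, 33.92, 39.68, 34.11, 39.38, 33.99),
               s_initial = c(14.70, 13.98, 14.34, 14.22, 14.16, 14.45, 14.52))
  )
  rownames(rows) <- NULL
  rows
}
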