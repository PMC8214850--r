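#' Detection-event summary of the Gran Sabana camera-trap survey
#'
#' Per-species detection-event counts (D) and printed frequency-of-detection
#' values (FD, events per 100 camera-days) for the 25 mammal and 15 bird
#' species recorded by the survey; total effort was 4,548 camera-days.
#' Used as a worked example and as a cross-check of the FD arithmetic.
#'
#' @return data frame with columns `species`, `class`, `FD`, `D`.
#' @export
gran_sabana_detections <- function() {
  m <- rbind(
    c("red_brocket",                 0.44,  20),
    c("gray_brocket",                1.03,  47),
    c("white_tailed_deer",           0.09,   4),
    c("collared_peccary",            0.04,   2),
    c("white_lipped_peccary",        0.04,   2),
    c("margay",                      0.04,   2),
    c("ocelot",                      0.33,  15),
    c("jaguar",                      0.31,  14),
    c("puma",                        0.24,  11),
    c("crab_eating_fox",             0.97,  44),
    c("tayra",                       0.46,  21),
    c("south_american_coati",        0.18,   8),
    c("greater_long_nosed_armadillo",0.75,  34),
    c("nine_banded_armadillo",       0.42,  19),
    c("naked_tailed_armadillo",      0.04,   2),
    c("giant_armadillo",             0.18,   8),
    c("south_american_tapir",        0.31,  14),
    c("white_eared_opossum",         0.31,  14),
    c("common_opossum",              0.04,   2),
    c("southern_tamandua",           0.13,   6),
    c("giant_anteater",              0.33,  15),
    c("lowland_paca",                5.83, 265),
    c("red_rumped_agouti",           4.20, 191),
    c("capybara",                    0.07,   3),
    c("wedge_capped_capuchin",       0.18,   8))
  b <- rbind(
    c("pectoral_sparrow",            0.18,   8),
    c("savanna_hawk",                0.02,   1),
    c("turkey_vulture",              0.04,   2),
    c("black_curassow",              1.06,  48),
    c("tinamous_spp",                0.04,   2),
    c("variegated_tinamou",          0.15,   7),
    c("little_tinamou",              0.24,  11),
    c("ruddy_quail_dove",            0.02,   1),
    c("grey_fronted_dove",           1.50,  68),
    c("green_ibis",                  0.02,   1),
    c("tropical_mockingbird",        0.24,  11),
    c("rufous_winged_ground_cuckoo", 0.02,   1),
    c("spix_guan",                   0.18,   8),
    c("great_tinamou",               0.53,  24),
    c("white_necked_thrush",         0.73,  33))
  data.frame(
    species = c(m[, 1], b[, 1]),
    class = rep(c("mammal", "bird"), c(nrow(m), nrow(b))),
    FD = as.numeric(c(m[, 2], b[, 2])),
    D = as.integer(c(m[, 3], b[, 3])),
    stringsAsFactors = FALSE)
}

#' Total camera-trapping effort of the Gran Sabana survey, in camera-days
#' @export
gran_sabana_effort <- function() 4548

#' Community-level hunting preference tables
#'
#' Interview tallies from the four Pemon communities: preferred hunting
#' habitat (forest / savanna / mixed) and preferred hunting season (all
#' year / rainy season / no preference). Worked examples for
#' [chi2_contingency()].
#'
#' @return list of two integer matrices, `habitat` and `season`, with
#'   communities as rows.
#' @export
hunting_preference_tables <- function() {
  communities <- c("Kami", "Mare Paru", "Uroy-Uaray", "Wuarapata")
  habitat <- matrix(c(4, 1, 2,
                      5, 0, 0,
                      4, 5, 4,
                      8, 3, 4), nrow = 4, byrow = TRUE,
                    dimnames = list(communities,
                                    c("forest", "savanna", "mixed")))
  season <- matrix(c(1, 2, 1,
                     1, 5, 0,
                     3, 2, 2,
                     1, 10, 0), nrow = 4, byrow = TRUE,
                   dimnames = list(communities,
                                   c("all_year", "rainy", "none")))
  list(habitat = habitat, season = season)
}
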