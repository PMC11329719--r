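#' Reference cluster-by-covariate cross-tabulations
#'
#' Contingency tables and cluster sizes reported for a published multi-cohort
#' PD subtyping analysis: a three-cluster solution obtained without global
#' atrophy adjustment and an eight-cluster solution (retained from ten after
#' the minimum-size filter) obtained with it. Rows are clusters (cl1, cl2,
#' ...), columns the variable categories. These printed counts serve as fixed
#' inputs for exercising [chi_square_table()] and
#' [filter_small_clusters()] against their published statistics; they are not
#' subject-level data.
#'
#' @return List with elements `three_cluster` and `eight_cluster` (each a
#'   list of count matrices plus `reported_chisq`), `ten_cluster_sizes`, and
#'   `three_cluster_sizes`.
#' @export
reference_cluster_tables <- function() {
  m3 <- function(...) matrix(c(...), nrow = 3, byrow = TRUE)
  m8 <- function(...) matrix(c(...), nrow = 8, byrow = TRUE)
  three <- list(
    sex = m3(190, 112,  88, 60, 123, 60),
    hy_stage = m3(85, 2, 174, 5, 22, 6,
                  57, 2,  73, 2,  7, 2,
                  48, 1, 102, 5, 19, 2),
    medicated = m3(117, 184, 60, 88, 81, 102),
    mci = m3(47, 184, 13, 96, 38, 99),
    depression = m3(47, 185, 26, 85, 32, 110),
    rbd = m3(55, 99, 27, 44, 37, 52),
    cohort = m3(46, 40, 61, 155,
                26, 15, 36,  71,
                35, 20, 39,  89),
    reported_chisq = c(sex = 2.166, hy_stage = 12.013, medicated = 1.376,
                       mci = 9.307, depression = 0.536, rbd = 0.823,
                       cohort = 3.148)
  )
  eight <- list(
    sex = m8(51, 5, 145, 44, 40, 22, 75, 92, 37, 14, 19, 27, 15, 4, 18, 16),
    hy_stage = m8(19, 0, 32, 1,  2, 1,
                  58, 2, 99, 2, 19, 2,
                  12, 1, 40, 2,  5, 1,
                  45, 0, 90, 6, 13, 5,
                  15, 1, 33, 0,  2, 0,
                  14, 1, 26, 0,  4, 1,
                  11, 0,  7, 0,  1, 0,
                  14, 0, 15, 1,  2, 0),
    medicated = m8(28, 28, 79, 110, 26, 36, 74, 93, 17, 34, 21, 25, 5, 14,
                   7, 26),
    mci = m8(8, 40, 33, 105, 12, 31, 23, 96, 11, 33, 6, 32, 2, 12, 3, 21),
    depression = m8(7, 40, 23, 114, 12, 35, 36, 88, 9, 35, 10, 28, 1, 13,
                    5, 20),
    rbd = m8(12, 14, 40, 51, 10, 20, 34, 41, 6, 26, 5, 15, 2, 10, 7, 13),
    cohort = m8(16,  8,  6, 26,
                24, 25, 49, 91,
                13,  5, 14, 30,
                31, 21, 39, 76,
                 8,  5,  6, 32,
                10,  8,  8, 20,
                 2,  0,  5, 12,
                 2,  3,  9, 20),
    reported_chisq = c(sex = 73.143, hy_stage = 32.097, medicated = 11.353,
                       mci = 5.168, depression = 9.881, rbd = 12.966,
                       cohort = 28.416)
  )
  list(three_cluster = three, eight_cluster = eight,
       ten_cluster_sizes = c(56, 189, 62, 167, 51, 46, 19, 34, 8, 1),
       three_cluster_sizes = c(302, 148, 183))
}
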