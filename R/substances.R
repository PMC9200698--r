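#' Substance property table
#'
#' Constructor/validator for the substance property table used across the
#' pipeline: limit of quantification, Freundlich sorption coefficient
#' normalised to organic carbon, octanol-water partition coefficient
#' (log10), and soil/water half-lives.
#'
#' @param name substance name.
#' @param loq limit of quantification (ng/L), > 0.
#' @param kfoc Freundlich sorption coefficient (L/kg).
#' @param log_kow log10 octanol-water partition coefficient.
#' @param dt50_soil,dt50_water half-lives (days), > 0.
#' @param is_tp transformation-product flag.
#' @return Data frame of class `substance_properties`.
#' @export
substance_properties <- function(name, loq, kfoc, log_kow, dt50_soil,
                                 dt50_water, is_tp = FALSE) {
  stopifnot(all(loq > 0), all(dt50_soil > 0), all(dt50_water > 0))
  out <- data.frame(name = name, loq = loq, kfoc = kfoc,
                    log_kow = log_kow, dt50_soil = dt50_soil,
                    dt50_water = dt50_water,
                    is_tp = rep_len(is_tp, length(name)))
  class(out) <- c("substance_properties", "data.frame")
  out
}

#' Default synthetic substance set
#'
#' Twenty substances (18 parent pesticides, 2 transformation products) with
#' synthetic property values chosen to span the ranges observed in arable
#' cropping: soil half-lives from a few days to > 270 days, sorption over
#' three orders of magnitude, and LOQs around 20 ng/L. The values are
#' plausible stand-ins of PPDB-style properties, not measured data.
#'
#' @return A [substance_properties()] table.
#' @export
default_substances <- function() {
  substance_properties(
    name = c("metamitron", "ethofumesate", "terbuthylazine", "propamocarb",
             "epoxiconazole", "pencycuron", "metribuzin", "bixafen",
             "fluopicolide", "napropamide", "prosulfocarb", "diflufenican",
             "metrafenone", "cymoxanil", "isoproturon", "chlortoluron",
             "mecoprop", "propiconazole",
             "chloridazon-desphenyl", "metolachlor-ESA"),
    loq = c(20, 20, 10, 50, 20, 20, 20, 20, 20, 20, 20, 10,
            20, 20, 10, 20, 20, 20, 50, 20),
    kfoc = c(78, 147, 231, 672, 1073, 2200, 38, 1500, 321, 839, 1693,
             1996, 2873, 43, 122, 196, 47, 1086, 89, 25),
    log_kow = c(0.85, 2.7, 3.4, 0.84, 3.3, 4.68, 1.65, 3.3, 2.9, 3.3,
                4.48, 4.2, 4.3, 0.67, 2.5, 2.5, 0.02, 3.72, -0.9, -1.3),
    dt50_soil = c(19, 22, 72, 39, 120, 107, 12, 200, 320, 300, 10, 142,
                  250, 3, 12, 34, 8, 71, 150, 290),
    dt50_water = c(11, 20, 46, 60, 44, 30, 7, 50, 100, 30, 7, 80, 100,
                   1, 30, 45, 14, 30, 120, 200),
    is_tp = c(rep(FALSE, 18), TRUE, TRUE))
}
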