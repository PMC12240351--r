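#' Printed degree-pair edge partition of Oxaliplatin
#'
#' The hydrogen-suppressed Oxaliplatin graph has 15 heavy atoms and 17 bonds;
#' its published degree-pair partition is
#' \{(1,3): 2, (2,3): 6, (2,2): 3, (2,4): 4, (3,3): 2\}.
#'
#' @return a tibble with columns `du`, `dv`, `count`.
#' @export
oxaliplatin_partition <- function() {
  partition_from_counts(tibble::tibble(
    du = c(1L, 2L, 2L, 2L, 3L),
    dv = c(3L, 2L, 3L, 4L, 3L),
    count = c(2L, 3L, 6L, 4L, 2L)
  ))
}

#' Entropy descriptors of the fourteen colorectal-cancer drugs
#'
#' The published per-drug values of the ten entropy indices, as printed
#' (values are transcribed verbatim; two known anomalies -- the
#' geometric-arithmetic entropies of Carboplatin and Fluorouracil exceed the
#' \eqn{\ln m} bound implied by any plausible bond count -- are kept as data).
#' Drug names are normalized to one standard spelling so that this table joins
#' with [crc_properties()].
#'
#' @return a tibble: `compound` plus columns `Ent_ABC` ... `Ent_R`.
#' @export
crc_descriptors <- function() {
  tibble::tribble(
    ~compound, ~Ent_ABC, ~Ent_F, ~Ent_GA, ~Ent_H, ~Ent_ISI, ~Ent_M1, ~Ent_M2, ~Ent_S, ~Ent_SO, ~Ent_R,
    "Adagrasib",      3.8696, 3.8292, 3.87,   3.8571, 3.8504,  3.8582, 3.81,   3.8677, 3.8601, 3.8528,
    "Bisoxatin",      3.3305, 3.2658, 3.3315, 3.3177, 3.2823,  3.3154, 3.253,  3.3284, 3.3163, 3.3147,
    "Capecitabine",   3.2554, 3.2124, 3.256,  3.2412, 3.1868,  3.242,  3.1729, 3.2539, 3.246,  3.2337,
    "Carboplatin",    2.635,  2.4352, 3.3295, 2.6199, 2.602,   2.62,   2.539,  2.634,  2.622,  2.614,
    "Docetaxel",      4.1384, 4.0772, 4.1404, 4.1251, 4.1041,  4.1237, 4.0354, 4.1385, 4.1264, 4.1177,
    "Fluorouracil",   2.194,  2.1717, 2.888,  2.188,  2.169,   2.187,  2.1284, 2.1948, 2.1909, 2.1795,
    "Fruquintinib",   3.4646, 3.4192, 3.4651, 3.44501, 3.4353, 3.4501, 3.4002, 3.4609, 3.4523, 3.4401,
    "Irinotecan HCl", 3.8901, 3.8369, 3.8909, 3.8733, 3.868,   3.8757, 3.8212, 3.8874, 3.8772, 3.8695,
    "Leucovorin Ca",  3.5813, 3.5476, 3.5822, 3.57,   3.5582,  3.5711, 3.5164, 3.5801, 3.5634, 3.5634,
    "Olsalazine",     3.1328, 3.1049, 3.1338, 3.1247, 3.1082,  3.1242, 3.0663, 3.1327, 3.1278, 3.1168,
    "Oxaliplatin",    2.8317, 2.7843, 2.8323, 2.8198, 2.816,   2.82,   2.7807, 2.8299, 2.8204, 2.8169,
    "Regorafenib",    3.5523, 3.5161, 3.5532, 3.543,  3.5316,  3.5442, 3.4946, 3.5523, 3.5451, 3.4903,
    "Tipiracil",      2.8306, 2.8043, 2.8317, 2.823,  2.8077,  2.8226, 2.7686, 2.8306, 2.8259, 2.8151,
    "Trifluridine",   3.0391, 3.0028, 3.0416, 3.0315, 3.0084,  3.0302, 2.9596, 3.0404, 3.033,  3.019
  )
}

#' Physicochemical properties of the fourteen colorectal-cancer drugs
#'
#' Published property values: molecular weight (`MW`, g/mol), topological
#' surface area (`TSA`, A^2), complexity (`C`), density (`D`, g/cm^3), molar
#' volume (`MV`, cm^3), polarizability (`P`, 10^-24 cm^3) and molar
#' refractivity (`MR`, cm^3/mol).
#'
#' @return a tibble: `compound` plus the seven property columns.
#' @export
crc_properties <- function() {
  tibble::tribble(
    ~compound, ~MW, ~TSA, ~C, ~D, ~MV, ~P, ~MR,
    "Adagrasib",      604.1,  88.8,  1060, 1.3,  466.2, 64.8,  166.79,
    "Bisoxatin",      333.3,  78.8,  458,  1.4,  243.5, 36.3,  91.5,
    "Capecitabine",   359.35, 121,   582,  1.59, 240.5, 32.6,  82.3,
    "Carboplatin",    371.25, 82.3,  153,  1.7,  218,   18.27, 60.04,
    "Docetaxel",      807.9,  224,   1660, 1.4,  585.7, 81.4,  205.2,
    "Fluorouracil",   130.08, 58.2,  199,  1.5,  84.6,  9.46,  26.17,
    "Fruquintinib",   393.4,  95.7,  579,  1.3,  302.1, 43.1,  108.7,
    "Irinotecan HCl", 623.1,  113,   1200, 1.4,  416.8, 63.1,  159.1,
    "Leucovorin Ca",  511.5,  221,   900,  1.81, 281,   46.33, 126.66,
    "Olsalazine",     302.24, 140,   415,  1.6,  194.1, 29,    73.2,
    "Oxaliplatin",    397.3,  132,   124,  1.5,  265,   21.9,  67.52,
    "Regorafenib",    482.8,  92.4,  686,  1.5,  323.7, 44.8,  113.1,
    "Tipiracil",      242.66, 85.3,  404,  1.7,  141.4, 22.7,  57.2,
    "Trifluridine",   296.2,  99.1,  464,  1.6,  179.9, 22.2,  55.9
  )
}

#' Entropy descriptors of the external validation compounds
#'
#' Published entropy-index values of Erbitux and Larotrectinib, the two
#' held-out compounds used to check model validity.
#'
#' @return a tibble: `compound` plus columns `Ent_ABC` ... `Ent_R`.
#' @export
crc_validation_descriptors <- function() {
  tibble::tribble(
    ~compound, ~Ent_ABC, ~Ent_F, ~Ent_GA, ~Ent_H, ~Ent_ISI, ~Ent_M1, ~Ent_M2, ~Ent_S, ~Ent_SO, ~Ent_R,
    "Erbitux",       3.04, 2.9432, 3.042, 3.028, 3.01,  3.025, 2.939, 3.04, 3.025, 3.024,
    "Larotrectinib", 3.55, 3.524,  3.55,  3.54,  3.538, 3.545, 3.505, 3.55, 3.547, 3.54
  )
}

#' Physicochemical properties of the external validation compounds
#'
#' @return a tibble: `compound`, `MW`, `C`, `TSA`, `P`, `MR`.
#' @export
crc_validation_properties <- function() {
  tibble::tribble(
    ~compound, ~MW, ~C, ~TSA, ~P, ~MR,
    "Erbitux",       273.37, 375, 40.5, 27.5,  69.5,
    "Larotrectinib", 428.4,  659, 86,   41.61, 122.96
  )
}

#' Published best-fit cubic validation models
#'
#' The six literature-coefficient cubic models used for the
#' experimental-versus-calculated comparison on the held-out compounds.  These
#' are first-class model inputs (see [qspr_model()]), so validation never
#' depends on regenerating the training structures.
#'
#' @return a named list of [qspr_model()] objects.
#' @export
crc_validation_models <- function() {
  list(
    MW_EntISI = qspr_model("cubic", a = 323.0, b = c(18.4, -75.9, 24.7),
                           property = "MW", descriptor = "Ent_ISI"),
    C_EntF    = qspr_model("cubic", a = 756.7, b = c(4.4, -309.8, 88.3),
                           property = "C", descriptor = "Ent_F"),
    C_EntR    = qspr_model("cubic", a = 724.6, b = c(2.1, -295.3, 84.4),
                           property = "C", descriptor = "Ent_R"),
    P_EntR    = qspr_model("cubic", a = 13.8, b = c(1.7, -5.8, 2.4),
                           property = "P", descriptor = "Ent_R"),
    MR_EntISI = qspr_model("cubic", a = 47.3, b = c(4.6, -16.4, 6.3),
                           property = "MR", descriptor = "Ent_ISI"),
    MR_EntR   = qspr_model("cubic", a = 46.6, b = c(3.7, -16.3, 6.2),
                           property = "MR", descriptor = "Ent_R")
  )
}
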