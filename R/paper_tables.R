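# Built-in bookkeeping tables for the published 20-scan mammalian long-bone
# dataset (river otter, capybara, leopard, sea otter, laboratory mouse).
# These are inputs to patch bookkeeping and fold construction; the scans
# themselves are not bundled.

#' Tile counts of the published 20-scan dataset
#'
#' Number of 2D tiles (slices) per scan of the published deep-learning
#' dataset, keyed by scan id.
#'
#' @return Named integer vector of length 20.
#' @export
bone_tile_counts <- function() {
  c(
    `1R_1U_HF` = 1792L,
    `2R_2U_HF` = 2112L,
    `5R_5U_HF` = 2048L,
    `7R_7U_HF` = 2048L,
    `12R_12U_HF` = 2048L,
    `19R_19U_HF` = 1920L,
    `AMNH_Mammals_M-89009_F` = 4250L,
    `AMNH_Mammals_M-206440_mixed` = 1672L,
    `OMNH_Mammals_44262_HRU` = 1662L,
    `OMNH_Mammals_53994_FTFi` = 2216L,
    `OMNH_Mammals_53994_HRU` = 1809L,
    `UAM_Mamm_24789_FTFi` = 2098L,
    `UAM_Mamm_67696_HF` = 1623L,
    `UAM_Mamm_67696_TFiRU` = 2321L,
    `UF_Mammals_23593-24550_HF` = 1755L,
    `UF_Mammals_31151_HRU` = 1660L,
    `UWBM_Mamm_78743_FTFi` = 2150L,
    `UWBM_Mamm_81969_FTFi` = 2195L,
    `UWBM_Mamm_81969_HRU` = 1995L,
    `ZMB_Mam_30740_HRU` = 3609L
  )
}

#' Fixed cross-validation order of the published 20-scan dataset
#'
#' The scans were randomized once and then frozen in this order before
#' partitioning into five consecutive test folds of four scans each; the
#' training/validation pool of fold i is the complement in sequence order
#' (pool 1 = positions 5-20).
#'
#' @return Character vector of 20 scan ids in fixed order.
#' @export
bone_fold_order <- function() {
  c(
    "UF_Mammals_31151_HRU",
    "OMNH_Mammals_44262_HRU",
    "2R_2U_HF",
    "OMNH_Mammals_53994_HRU",
    "UWBM_Mamm_81969_HRU",
    "UWBM_Mamm_78743_FTFi",
    "12R_12U_HF",
    "AMNH_Mammals_M-206440_mixed",
    "OMNH_Mammals_53994_FTFi",
    "UWBM_Mamm_81969_FTFi",
    "UF_Mammals_23593-24550_HF",
    "UAM_Mamm_67696_HF",
    "19R_19U_HF",
    "1R_1U_HF",
    "AMNH_Mammals_M-89009_F",
    "7R_7U_HF",
    "UAM_Mamm_24789_FTFi",
    "5R_5U_HF",
    "ZMB_Mam_30740_HRU",
    "UAM_Mamm_67696_TFiRU"
  )
}
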