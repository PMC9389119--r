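# Feature values used by the fixture cohorts: each sits a >= 10% margin
# away from the corresponding default decision cutoff (7.02, 12.53,
# 132.73, grade 3) so boundary-handling changes cannot flip a call.
FIXTURE_LEVELS <- list(
  suv_pos = 7.80, suv_neg = 6.30,
  tlg_pos = 13.90, tlg_neg = 11.20,
  hue_pos = 146.10, hue_neg = 119.40,
  grade_pos = 4L, grade_neg = 2L
)

fixture_rows <- function(n, true_class, diagnosis, pet_pos, ela_pos,
                         station) {
  if (n == 0L) return(NULL)
  lv <- FIXTURE_LEVELS
  data.frame(
    station = rep_len(station, n),
    short_axis_mm = ifelse(rep(pet_pos, n), 14, 9),
    true_class = true_class, diagnosis = diagnosis,
    suv_max = if (pet_pos) lv$suv_pos else lv$suv_neg,
    tlg = if (pet_pos) lv$tlg_pos else lv$tlg_neg,
    mean_hue = if (ela_pos) lv$hue_pos else lv$hue_neg,
    grade = if (ela_pos) lv$grade_pos else lv$grade_neg,
    stringsAsFactors = FALSE
  )
}

finish_fixture <- function(blocks, prefix) {
  df <- do.call(rbind, blocks)
  rownames(df) <- NULL
  df <- cbind(node_id = sprintf("%s%03d", prefix, seq_len(nrow(df))),
              patient_id = sprintf("%sP%03d", prefix, seq_len(nrow(df))),
              df, stringsAsFactors = FALSE)
  df
}

#' Deterministic 53-node validation fixture
#'
#' A fixed cohort of 36 malignant and 17 benign nodes whose features,
#' classified with the default [rule_cutoffs()], yield exactly the
#' reference validation-group confusion counts: PET/CT FP = 13 / FN = 0,
#' elastography FP = 5 / FN = 2, combined FP = 4 / FN = 2. The benign
#' false-positive composition follows the reported breakdown (8 of 12
#' nonspecific lymphadenitis, all 3 sarcoidosis and both tuberculosis
#' nodes PET-positive; 9 of the 13 PET false positives
#' elastography-negative). Feature values are synthetic by construction;
#' only the induced counts are anchored.
#'
#' @return `data.frame` with one row per node.
#' @export
validation_fixture <- function() {
  b <- list(
    # --- malignant, all PET-positive (FN = 0) ---
    # elastography-negative malignant (FN = 2): 1 adeno, 1 neuroendocrine
    fixture_rows(1, "malignant", "adenocarcinoma", TRUE, FALSE, "4R"),
    fixture_rows(1, "malignant", "neuroendocrine_tumor_nos", TRUE, FALSE, "4R"),
    fixture_rows(17, "malignant", "adenocarcinoma", TRUE, TRUE,
                 c("4R", "7", "4L")),
    fixture_rows(6, "malignant", "squamous_carcinoma", TRUE, TRUE, "7"),
    fixture_rows(1, "malignant", "nsclc_not_otherwise_specified", TRUE, TRUE, "7"),
    fixture_rows(5, "malignant", "small_cell_lung_cancer", TRUE, TRUE, "11L"),
    fixture_rows(2, "malignant", "neuroendocrine_tumor_nos", TRUE, TRUE, "4R"),
    fixture_rows(2, "malignant", "lung_cancer_unknown_type", TRUE, TRUE, "10R"),
    fixture_rows(1, "malignant", "lymphoma", TRUE, TRUE, "7"),
    # --- benign: 13 PET-positive, 5 elasto-positive, 4 both-positive ---
    fixture_rows(2, "benign", "nonspecific_lymphadenitis", TRUE, TRUE, "4R"),
    fixture_rows(6, "benign", "nonspecific_lymphadenitis", TRUE, FALSE, "7"),
    fixture_rows(1, "benign", "nonspecific_lymphadenitis", FALSE, TRUE, "4L"),
    fixture_rows(3, "benign", "nonspecific_lymphadenitis", FALSE, FALSE, "7"),
    fixture_rows(1, "benign", "sarcoidosis", TRUE, TRUE, "7"),
    fixture_rows(2, "benign", "sarcoidosis", TRUE, FALSE, "4R"),
    fixture_rows(1, "benign", "tuberculosis", TRUE, TRUE, "4R"),
    fixture_rows(1, "benign", "tuberculosis", TRUE, FALSE, "7")
  )
  finish_fixture(b, "V")
}

#' Deterministic 154-node model fixture
#'
#' A fixed cohort of 92 malignant and 62 benign nodes that, under the
#' default [rule_cutoffs()], yields exactly the reference model-group
#' confusion counts: PET/CT (TP 86, FP 26, FN 6, TN 36), elastography
#' (TP 82, FP 12, FN 10, TN 50) and combined (TP 79, FP 7, FN 13,
#' TN 55). Among the 26 PET/CT false positives, 19 are
#' elastography-negative, and the per-diagnosis composition follows the
#' reported breakdown (19 nonspecific lymphadenitis, 4 of 7 sarcoidosis,
#' both tuberculosis nodes and the single non-tuberculous mycobacterium
#' node PET-positive). Diagnosis totals match the reference cohort table.
#'
#' @return `data.frame` with one row per node.
#' @export
model_fixture <- function() {
  # malignant joint calls: both+ 79, pet+/ela- 7, pet-/ela+ 3, both- 3
  mal_diag <- rep(names(MALIGNANT_DIAGNOSES), MALIGNANT_DIAGNOSES)
  mal_pet <- rep(c(TRUE, TRUE, FALSE, FALSE), c(79, 7, 3, 3))
  mal_ela <- rep(c(TRUE, FALSE, TRUE, FALSE), c(79, 7, 3, 3))
  # benign joint calls: both+ 7, pet+/ela- 19, pet-/ela+ 5, both- 31,
  # with PET+ composition 19 lymphadenitis + 4 sarcoid + 2 TB + 1 NTM
  ben <- rbind(
    data.frame(diagnosis = "nonspecific_lymphadenitis",
               pet = rep(c(TRUE, TRUE, FALSE, FALSE), c(4, 15, 5, 28))),
    data.frame(diagnosis = "sarcoidosis",
               pet = rep(c(TRUE, TRUE, FALSE), c(1, 3, 3))),
    data.frame(diagnosis = "tuberculosis", pet = c(TRUE, TRUE)),
    data.frame(diagnosis = "ntm_infection", pet = TRUE)
  )
  ben$ela <- c(rep(c(TRUE, FALSE, TRUE, FALSE), c(4, 15, 5, 28)),
               rep(c(TRUE, FALSE, FALSE), c(1, 3, 3)),
               c(TRUE, FALSE), TRUE)
  stations <- rep(names(STATION_COUNTS), STATION_COUNTS)
  rows <- c(
    Map(function(d, p, e) fixture_rows(1, "malignant", d, p, e, "7"),
        mal_diag, mal_pet, mal_ela),
    Map(function(d, p, e) fixture_rows(1, "benign", d, p, e, "7"),
        ben$diagnosis, ben$pet, ben$ela)
  )
  df <- finish_fixture(rows, "M")
  df$station <- stations[seq_len(nrow(df))]
  df
}
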