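# Criterion taxonomy and the measure registry.
#
# The ND-PAE rules operate on 12 criteria partitioned into three domains:
#   NI (neurocognitive, 5), SR (self-regulation, 3), AF (adaptive
#   functioning, 4). Column order of every criterion matrix is fixed to the
# order below.

.criteria <- data.frame(
  criterion = c("global_intellectual", "executive_function", "learning",
                "memory", "visual_spatial",
                "mood_behavior", "attention", "impulse_control",
                "communication", "social", "daily_living", "motor"),
  domain = rep(c("NI", "SR", "AF"), times = c(5, 3, 4)),
  label = c("Global intellectual functioning", "Executive functioning",
            "Learning", "Memory", "Visual-spatial reasoning",
            "Mood/behavioral regulation", "Attention", "Impulse control",
            "Communication", "Social communication", "Daily living skills",
            "Motor skills"),
  stringsAsFactors = FALSE
)

.scales <- c("standard_100_15", "t_50_10", "scaled_10_3", "z", "binary")
.orientations <- c("higher_better", "higher_worse", "binary_impaired")

#' The 12 ND-PAE criteria and their domains
#'
#' Returns the fixed criterion taxonomy: five neurocognitive (NI), three
#' self-regulation (SR), and four adaptive-functioning (AF) criteria, in the
#' canonical column order used by [criterion_matrix()].
#'
#' @return A data frame with columns `criterion`, `domain` (`"NI"`, `"SR"`,
#'   `"AF"`), and `label`.
#' @export
#' @examples
#' ndpae_criteria()
ndpae_criteria <- function() .criteria

#' Domain of one or more criteria
#'
#' @param criterion Character vector of criterion ids.
#' @return Character vector of domains (`"NI"`, `"SR"`, `"AF"`).
#' @export
criterion_domain <- function(criterion) {
  idx <- match(criterion, .criteria$criterion)
  if (anyNA(idx)) {
    stop("unknown criterion id(s): ",
         paste(criterion[is.na(idx)], collapse = ", "))
  }
  .criteria$domain[idx]
}

#' Construct a measure specification
#'
#' Binds one instrument score to one ND-PAE criterion, recording the normed
#' scale it is reported on and its orientation (whether higher raw scores
#' mean stronger or weaker functioning). Binary instruments (which emit 1 =
#' impaired / 0 = not) must use the `binary` scale with `binary_impaired`
#' orientation, and vice versa.
#'
#' @param measure_id Unique measure identifier (column name in cohort CSVs).
#' @param criterion One of the 12 ids in [ndpae_criteria()].
#' @param scale One of `"standard_100_15"` (M=100, SD=15), `"t_50_10"`
#'   (M=50, SD=10), `"scaled_10_3"` (M=10, SD=3), `"z"`, `"binary"`.
#' @param orientation `"higher_better"`, `"higher_worse"`, or
#'   `"binary_impaired"`.
#' @return A one-row data frame of class `ndpae_registry`.
#' @export
#' @examples
#' measure_spec("wisc_fsiq", "global_intellectual",
#'              "standard_100_15", "higher_better")
measure_spec <- function(measure_id, criterion, scale, orientation) {
  stopifnot(is.character(measure_id), length(measure_id) == 1L,
            nzchar(measure_id))
  if (!criterion %in% .criteria$criterion)
    stop("unknown criterion: ", criterion)
  scale <- match.arg(scale, .scales)
  orientation <- match.arg(orientation, .orientations)
  if (xor(scale == "binary", orientation == "binary_impaired"))
    stop("binary scale and binary_impaired orientation must be used together")
  out <- data.frame(measure_id = measure_id, criterion = criterion,
                    scale = scale, orientation = orientation,
                    stringsAsFactors = FALSE)
  class(out) <- c("ndpae_registry", "data.frame")
  out
}

as_registry <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("measure_id", "criterion", "scale", "orientation")
                %in% names(x)))
  if (anyDuplicated(x$measure_id))
    stop("duplicate measure_id in registry")
  bad <- !x$criterion %in% .criteria$criterion
  if (any(bad)) stop("unknown criterion: ",
                     paste(unique(x$criterion[bad]), collapse = ", "))
  if (any(xor(x$scale == "binary", x$orientation == "binary_impaired")))
    stop("binary scale and binary_impaired orientation must be paired")
  class(x) <- c("ndpae_registry", "data.frame")
  x
}

reg_row <- function(id, crit, scale, orient) {
  data.frame(measure_id = id, criterion = crit, scale = scale,
             orientation = orient, stringsAsFactors = FALSE)
}

#' Default measure registry for the CIFASD neuropsychological battery
#'
#' One entry per instrument-score family used to assess each criterion:
#' IQ-type composites are standard scores (M=100, SD=15) where higher is
#' better; behavior-problem scales (BRIEF, CBCL, Conners 3, BASC-3 problem
#' scales, TRF) are T-scores (M=50, SD=10) where higher is worse; individual
#' cognitive subtests (D-KEFS, CVLT-C, NEPSY-II, CANTAB, NIH Toolbox,
#' WISC subtests) are scaled scores (M=10, SD=3) or z-scores where higher is
#' better; adaptive composites (VABS, BASC-3 adaptive scales) are standard
#' or T-type scores where higher is better; the DBD diagnosis flags are
#' binary (1 = impaired).
#'
#' @return An `ndpae_registry` data frame, one row per measure, covering all
#'   12 criteria.
#' @export
#' @examples
#' reg <- ndpae_registry()
#' table(reg$criterion)
ndpae_registry <- function() {
  rows <- list(
    # NI: global intellectual functioning
    reg_row("das2_gca",            "global_intellectual", "standard_100_15", "higher_better"),
    reg_row("wisc_fsiq",           "global_intellectual", "standard_100_15", "higher_better"),
    # NI: executive functioning
    reg_row("brief_gec",           "executive_function", "t_50_10",     "higher_worse"),
    reg_row("dkefs_vf_switching",  "executive_function", "scaled_10_3", "higher_better"),
    reg_row("dkefs_tm_switching",  "executive_function", "scaled_10_3", "higher_better"),
    reg_row("dkefs_design_fluency","executive_function", "scaled_10_3", "higher_better"),
    reg_row("dkefs_cwi_inh_switch","executive_function", "scaled_10_3", "higher_better"),
    reg_row("dkefs_twenty_q",      "executive_function", "scaled_10_3", "higher_better"),
    reg_row("dkefs_tower",         "executive_function", "scaled_10_3", "higher_better"),
    reg_row("dref_exec",           "executive_function", "t_50_10",     "higher_worse"),
    reg_row("nihtb_card_sort",     "executive_function", "standard_100_15", "higher_better"),
    # NI: learning
    reg_row("cbcl_school",         "learning", "t_50_10",     "higher_worse"),
    reg_row("cvlt_trials_total",   "learning", "scaled_10_3", "higher_better"),
    reg_row("cvlt_trial5_recall",  "learning", "z",           "higher_better"),
    reg_row("cvlt_learning_slope", "learning", "z",           "higher_better"),
    reg_row("cvlt_recall_consist", "learning", "z",           "higher_better"),
    reg_row("trf_academic",        "learning", "t_50_10",     "higher_worse"),
    reg_row("wiat_math_ps",        "learning", "standard_100_15", "higher_better"),
    reg_row("wiat_word_reading",   "learning", "standard_100_15", "higher_better"),
    # NI: memory
    reg_row("cantab_wm_composite", "memory", "z",           "higher_better"),
    reg_row("cantab_delayed_match","memory", "z",           "higher_better"),
    reg_row("cvlt_short_delay",    "memory", "z",           "higher_better"),
    reg_row("cvlt_long_delay",     "memory", "z",           "higher_better"),
    reg_row("nepsy_narrative_mem", "memory", "scaled_10_3", "higher_better"),
    reg_row("nepsy_mem_designs",   "memory", "scaled_10_3", "higher_better"),
    reg_row("nepsy_mem_names",     "memory", "scaled_10_3", "higher_better"),
    reg_row("nihtb_pic_seq_mem",   "memory", "standard_100_15", "higher_better"),
    reg_row("nihtb_list_sort_wm",  "memory", "standard_100_15", "higher_better"),
    reg_row("wisc_wm_composite",   "memory", "standard_100_15", "higher_better"),
    # NI: visual-spatial
    reg_row("cantab_spatial_wm",   "visual_spatial", "z",           "higher_better"),
    reg_row("wisc_block_design",   "visual_spatial", "scaled_10_3", "higher_better"),
    # SR: mood/behavioral regulation
    reg_row("basc_externalizing",  "mood_behavior", "t_50_10", "higher_worse"),
    reg_row("basc_internalizing",  "mood_behavior", "t_50_10", "higher_worse"),
    reg_row("brief_emot_control",  "mood_behavior", "t_50_10", "higher_worse"),
    reg_row("cbcl_anx_dep",        "mood_behavior", "t_50_10", "higher_worse"),
    reg_row("cbcl_withdrawn_dep",  "mood_behavior", "t_50_10", "higher_worse"),
    reg_row("vabs_externalizing",  "mood_behavior", "t_50_10", "higher_worse"),
    reg_row("vabs_internalizing",  "mood_behavior", "t_50_10", "higher_worse"),
    # SR: attention
    reg_row("basc_hyperactivity",  "attention", "t_50_10", "higher_worse"),
    reg_row("cbcl_attention",      "attention", "t_50_10", "higher_worse"),
    reg_row("conners_inattention", "attention", "t_50_10", "higher_worse"),
    reg_row("conners_adhd_inatt",  "attention", "t_50_10", "higher_worse"),
    reg_row("conners_adhd_hyp",    "attention", "t_50_10", "higher_worse"),
    reg_row("dbd_adhd_combined",   "attention", "binary",  "binary_impaired"),
    reg_row("nihtb_flanker",       "attention", "standard_100_15", "higher_better"),
    # SR: impulse control
    reg_row("basc_aggression",     "impulse_control", "t_50_10", "higher_worse"),
    reg_row("basc_conduct",        "impulse_control", "t_50_10", "higher_worse"),
    reg_row("cbcl_rule_breaking",  "impulse_control", "t_50_10", "higher_worse"),
    reg_row("conners_hyp_imp",     "impulse_control", "t_50_10", "higher_worse"),
    reg_row("conners_conduct",     "impulse_control", "t_50_10", "higher_worse"),
    reg_row("conners_odd",         "impulse_control", "t_50_10", "higher_worse"),
    reg_row("dbd_od_diag",         "impulse_control", "binary",  "binary_impaired"),
    reg_row("dbd_cd_diag",         "impulse_control", "binary",  "binary_impaired"),
    # AF: communication (BASC adaptive scales are T-scores, higher = better)
    reg_row("basc_func_comm",      "communication", "t_50_10",         "higher_better"),
    reg_row("vabs_communication",  "communication", "standard_100_15", "higher_better"),
    # AF: social communication (CBCL Social Problems is a problem scale)
    reg_row("basc_social_skills",  "social", "t_50_10",         "higher_better"),
    reg_row("cbcl_social_problems","social", "t_50_10",         "higher_worse"),
    reg_row("vabs_socialization",  "social", "standard_100_15", "higher_better"),
    # AF: daily living
    reg_row("basc_daily_living",   "daily_living", "t_50_10",         "higher_better"),
    reg_row("vabs_daily_living",   "daily_living", "standard_100_15", "higher_better"),
    # AF: motor
    reg_row("vabs_motor",          "motor", "standard_100_15", "higher_better")
  )
  as_registry(do.call(rbind, rows))
}
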