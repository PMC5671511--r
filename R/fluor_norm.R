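# Dual-reporter plate normalization: blank subtraction, per-well GFP/mCherry
# ratios (cancelling per-well transfection efficiency), replicate
# aggregation, reference scaling and significance.

PLATE_CHANNELS <- c("GFP", "mCherry")
PLATE_ROLES <- c("sample", "blank", "background")

#' Validate a plate data frame
#'
#' A plate holds one row per well x channel with columns `well`, `construct`
#' (empty/NA for blank and background wells), `role` (`sample`, `blank`,
#' `background`), `channel` (`GFP`, `mCherry`), `value`, and optionally
#' `transfection` (the biological-replicate label; absent means each well is
#' its own replicate). Every sample well must carry both channels and each
#' channel needs at least one blank well.
#'
#' @param plate Data frame as above.
#' @return The plate, invisibly, with class `plate` attached.
#' @export
as_plate <- function(plate) {
  need <- c("well", "construct", "role", "channel", "value")
  if (!is.data.frame(plate) || !all(need %in% names(plate))) {
    stop(sprintf("plate needs columns %s", paste(need, collapse = ", ")))
  }
  if (!all(plate$role %in% PLATE_ROLES)) {
    stop(sprintf("unknown role(s): %s",
                 paste(setdiff(unique(plate$role), PLATE_ROLES), collapse = ", ")))
  }
  if (!all(plate$channel %in% PLATE_CHANNELS)) {
    stop(sprintf("unknown channel(s): %s",
                 paste(setdiff(unique(plate$channel), PLATE_CHANNELS),
                       collapse = ", ")))
  }
  if (!is.numeric(plate$value) || anyNA(plate$value)) {
    stop("'value' must be numeric without NAs")
  }
  if (anyDuplicated(plate[, c("well", "channel")])) {
    stop("duplicate well x channel rows")
  }
  smp <- plate[plate$role == "sample", , drop = FALSE]
  if (nrow(smp)) {
    per_well <- table(smp$well)
    if (any(per_well != 2L)) {
      stop("every sample well must have exactly one GFP and one mCherry row")
    }
  }
  for (ch in PLATE_CHANNELS) {
    if (!any(plate$role == "blank" & plate$channel == ch)) {
      stop(sprintf("no blank well for channel %s", ch))
    }
  }
  if (!"transfection" %in% names(plate)) plate$transfection <- NA_character_
  class(plate) <- unique(c("plate", class(plate)))
  invisible(plate)
}

#' Subtract channel blanks from a plate
#'
#' Subtracts the per-channel blank aggregate (mean by default, as the
#' simplest unbiased choice; median available) from every well, blanks
#' included, so blank wells read about zero afterwards. Negative corrected
#' values are kept but flagged in the `negative` column.
#'
#' @param plate A plate data frame (see [as_plate()]).
#' @param aggregate `"mean"` or `"median"` blank aggregation.
#' @return The blank-corrected plate with columns `value` (corrected),
#'   `raw_value`, `negative`, and attributes `blank` (per-channel level) and
#'   `blank_corrected = TRUE`.
#' @export
blank_correct <- function(plate, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  plate <- as_plate(plate)
  agg <- if (aggregate == "mean") mean else stats::median
  blanks <- vapply(PLATE_CHANNELS, function(ch) {
    agg(plate$value[plate$role == "blank" & plate$channel == ch])
  }, numeric(1L))
  plate$raw_value <- plate$value
  plate$value <- plate$value - blanks[plate$channel]
  plate$negative <- plate$value < 0
  attr(plate, "blank") <- blanks
  attr(plate, "blank_corrected") <- TRUE
  plate
}

#' Per-well GFP/mCherry ratios
#'
#' Forms the transfection-efficiency-normalized ratio for each sample well
#' of a blank-corrected plate. Under the default rule, wells whose corrected
#' mCherry does not exceed the mean corrected mCherry of the background
#' (non-transfected) wells are excluded with reason "mCherry at background":
#' such wells carry no evidence of transfection, mirroring a no-promoter
#' control showing no signal above background.
#'
#' @param plate A blank-corrected plate (from [blank_correct()]).
#' @param background_rule `"exclude_below_background"` (default; requires
#'   background wells) or `"none"`.
#' @return A `ratio_table` data frame: `well`, `construct`, `transfection`,
#'   `gfp_corrected`, `mcherry_corrected`, `ratio` (NA when excluded),
#'   `excluded`, `reason`; attribute `background_mcherry` holds the
#'   threshold used.
#' @export
normalized_ratios <- function(plate,
                              background_rule = c("exclude_below_background",
                                                  "none")) {
  background_rule <- match.arg(background_rule)
  if (!isTRUE(attr(plate, "blank_corrected"))) {
    stop("plate must be blank-corrected first (see blank_correct())")
  }
  thr <- -Inf
  if (background_rule == "exclude_below_background") {
    bg <- plate$value[plate$role == "background" &
                        plate$channel == "mCherry"]
    if (length(bg) == 0L) {
      stop("background wells required by the exclusion rule are missing")
    }
    thr <- mean(bg)
  }
  smp <- plate[plate$role == "sample", , drop = FALSE]
  wide <- merge(
    smp[smp$channel == "GFP",
        c("well", "construct", "transfection", "value")],
    smp[smp$channel == "mCherry", c("well", "value")],
    by = "well", suffixes = c("_gfp", "_mch"))
  names(wide)[names(wide) == "value_gfp"] <- "gfp_corrected"
  names(wide)[names(wide) == "value_mch"] <- "mcherry_corrected"
  wide <- wide[order(wide$well), , drop = FALSE]
  excluded <- wide$mcherry_corrected <= thr
  wide$ratio <- ifelse(excluded, NA_real_,
                       wide$gfp_corrected / wide$mcherry_corrected)
  wide$excluded <- excluded
  wide$reason <- ifelse(excluded, "mCherry at background", "")
  rownames(wide) <- NULL
  structure(wide, background_mcherry = thr,
            class = c("ratio_table", "data.frame"))
}

#' Summarize constructs relative to a reference
#'
#' Aggregates a ratio table to construct level. The replication unit is the
#' transfection: wells of one transfection are averaged first, then the
#' construct mean, sd and coefficient of variation are taken over those
#' replicate values. `relative` scales each construct mean by the reference
#' mean times `scale` (the reference itself is exactly `scale`), and
#' `p_vs_reference` is a two-sided equal-variance two-sample Student's
#' t-test against the reference replicates (NA for the reference and for
#' constructs with fewer than 2 replicates, which are flagged).
#'
#' @param ratios A `ratio_table` from [normalized_ratios()].
#' @param reference Construct id of the reference; must have >= 2 replicates.
#' @param scale Reference scale constant, conventionally 1 or 100.
#' @param value Summarize the `"ratio"` (default) or the raw corrected
#'   `"gfp"` channel (useful to quantify what the normalization buys).
#' @return A `construct_summary` data frame: `construct`, `n`, `mean_ratio`,
#'   `sd_ratio`, `cv`, `relative`, `p_vs_reference`, `flag`.
#' @export
summarize_constructs <- function(ratios, reference, scale = 1,
                                 value = c("ratio", "gfp")) {
  value <- match.arg(value)
  stopifnot(inherits(ratios, "ratio_table"))
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("'scale' must be a positive number")
  }
  keep <- ratios[!ratios$excluded, , drop = FALSE]
  if (nrow(keep) == 0L) stop("all wells excluded")
  keep$y <- if (value == "ratio") keep$ratio else keep$gfp_corrected
  # replicate = per-transfection mean of its wells; wells lacking a
  # transfection label stand alone
  rep_id <- ifelse(is.na(keep$transfection), paste0("well:", keep$well),
                   keep$transfection)
  reps <- stats::aggregate(
    keep$y, by = list(construct = keep$construct, replicate = rep_id), mean)
  rep_values <- split(reps$x, reps$construct)
  if (!reference %in% names(rep_values)) {
    stop(sprintf("reference construct '%s' not present", reference))
  }
  ref <- rep_values[[reference]]
  if (length(ref) < 2L) stop("reference needs at least 2 replicates")
  out <- do.call(rbind, lapply(names(rep_values), function(cn) {
    v <- rep_values[[cn]]
    m <- mean(v)
    s <- if (length(v) >= 2L) stats::sd(v) else NA_real_
    p <- if (cn == reference) {
      NA_real_
    } else if (length(v) < 2L) {
      NA_real_
    } else {
      equal_var_t_test(v, ref)
    }
    data.frame(construct = cn, n = length(v), mean_ratio = m, sd_ratio = s,
               cv = s / m,
               relative = if (cn == reference) scale else m / mean(ref) * scale,
               p_vs_reference = p,
               flag = if (length(v) < 2L) "fewer than 2 replicates" else "",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, reference = reference, scale = scale, value = value,
            class = c("construct_summary", "data.frame"))
}

# two-sided pooled-variance t-test; constant data (which stats::t.test
# rejects) resolves to p = 1 when the means agree and p = 0 otherwise
equal_var_t_test <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * stats::var(x) +
                (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
  if (sp == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = TRUE)$p.value
}

#' Median coefficient of variation across constructs
#'
#' The between-replicate variability metric used to compare normalization
#' schemes: one c.v. per construct, summarized by the median.
#'
#' @param summary A `construct_summary` (or any data frame with a `cv`
#'   column).
#' @return Median of the defined construct c.v. values.
#' @export
median_cv <- function(summary) {
  if (!"cv" %in% names(summary)) stop("'summary' must have a 'cv' column")
  cv <- summary$cv[is.finite(summary$cv)]
  if (length(cv) == 0L) stop("no construct with a defined cv")
  stats::median(cv)
}
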