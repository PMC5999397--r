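# Grid-survey data model: the packaged transcription of the 46-sample
# screening tables, thickness/tilt aggregation with propagated measurement
# error, layer fractions, and the ideal / near-ideal classification.

#' Load the grid survey fixture
#'
#' Reads the packaged transcription of the 46-sample grid screening survey
#' (thickness ranges at hole centre/edge/substrate, layer tokens,
#' preferred-orientation calls, minimum layer-interface distances,
#' intentionally-thick flags, per-region interface/behavior/ice codes,
#' layer tilts and saturations) and returns one record per sample.
#' Ranges are stored as "lo-hi" strings with ASCII hyphens; "--" marks an
#' unmeasurable value; ";" separates recorded alternatives. The thickness
#' table skips sample 24 (tilt data only), so one record carries tilt
#' information alone.
#'
#' @param path directory containing survey_table1.csv / survey_table2.csv;
#'   defaults to the packaged fixture.
#' @return data.frame with one row per sample (46 rows), grid-family
#'   columns precomputed from the documented grid-type predicates.
#' @export
loadSurvey <- function(path = system.file("extdata", package = "iceProfiler")) {
  t1 <- utils::read.csv(file.path(path, "survey_table1.csv"),
                        stringsAsFactors = FALSE)
  t2 <- utils::read.csv(file.path(path, "survey_table2.csv"),
                        stringsAsFactors = FALSE)
  # schema validation with named row/column errors
  needed1 <- c("sample_id", "name", "grid_type", "t_center", "t_edge",
               "t_substrate", "layers_center", "layers_edge",
               "layers_substrate", "preferred_orientation",
               "min_layer_distance", "intentionally_thick", "affinity",
               "no_awi_interaction")
  miss <- setdiff(needed1, names(t1))
  if (length(miss)) stop("survey table 1 lacks column(s): ",
                         paste(miss, collapse = ", "))
  for (col in c("t_center", "t_edge", "t_substrate")) {
    for (i in seq_len(nrow(t1))) {
      tok <- t1[[col]][i]
      if (!is.na(tok) && tok != "--") {
        r <- parseRangeToken(tok)
        if (!is.null(r) && r[1] > r[2])
          stop("malformed range in sample ", t1$sample_id[i], ", column ",
               col, ": ", tok)
      }
    }
  }
  okOrient <- c("yes", "some", "no", "unknown")
  bad <- which(!t1$preferred_orientation %in% okOrient)
  if (length(bad))
    stop("invalid preferred_orientation token in sample ",
         t1$sample_id[bad[1]])
  rec <- merge(t2, t1, by = "sample_id", all = TRUE, sort = TRUE)
  rec$grid_family <- vapply(rec$grid_type, gridFamily, character(1))
  rec[order(rec$sample_id), ]
}

#' Grid-family predicate
#'
#' Maps a grid-type string to a survey family using documented substring
#' predicates: \emph{gold_spotiton} contains both Gold and Spotiton;
#' \emph{carbon_spotiton} contains Carbon and Spotiton (lacey, stripe and
#' holey carbon nanowire grids alike); \emph{carbon_conventional} contains
#' Carbon without Spotiton; \emph{gold_conventional} contains Gold without
#' Spotiton or Carbon.
#'
#' @param gridType character grid-type string.
#' @return family string ("other" when no predicate matches, NA input
#'   gives NA).
#' @export
gridFamily <- function(gridType) {
  if (is.na(gridType)) return(NA_character_)
  hasGold <- grepl("Gold", gridType, fixed = TRUE)
  hasCarbon <- grepl("Carbon", gridType, fixed = TRUE) ||
               grepl("CFlat", gridType, fixed = TRUE)
  spot <- grepl("Spotiton", gridType, fixed = TRUE)
  if (hasGold && spot) return("gold_spotiton")
  if (hasCarbon && spot) return("carbon_spotiton")
  if (hasCarbon) return("carbon_conventional")
  if (hasGold) return("gold_conventional")
  "other"
}

#' Parse a survey range token
#'
#' "30" gives c(30, 30); "25-95" gives c(25, 95); "--", "" and NA give
#' NULL. A decreasing range is returned as-is for the caller to reject.
#'
#' @param tok character token.
#' @return numeric(2) or NULL.
#' @export
parseRangeToken <- function(tok) {
  if (is.na(tok) || tok %in% c("--", "")) return(NULL)
  parts <- strsplit(tok, "-", fixed = TRUE)[[1]]
  parts <- suppressWarnings(as.numeric(parts))
  if (anyNA(parts)) return(NULL)
  if (length(parts) == 1) c(parts, parts) else parts[1:2]
}

# expand a tilt/saturation cell: ";"-separated alternatives, ranges to
# their midpoint, "--" dropped
.expandAngles <- function(tok) {
  if (is.na(tok) || tok == "") return(numeric(0))
  out <- numeric(0)
  for (alt in strsplit(tok, ";", fixed = TRUE)[[1]]) {
    r <- parseRangeToken(alt)
    if (!is.null(r)) out <- c(out, mean(r))
  }
  out
}

#' Propagate independent measurement errors
#'
#' delta_q = sqrt(sum(delta_x^2)) / N for independent random errors: N
#' equal per-measurement errors delta give delta / sqrt(N).
#'
#' @param errors per-measurement errors (>= 0, nonempty).
#' @return propagated error of the mean.
#' @examples
#' propagateMeasurementError(rep(5, 11))  # 5 / sqrt(11)
#' @export
propagateMeasurementError <- function(errors) {
  if (length(errors) == 0) stop("empty error list")
  stopifnot(all(errors >= 0))
  sqrt(sum(errors^2)) / length(errors)
}

.groupStat <- function(values, measErrorEach, sdType) {
  n <- length(values)
  m <- mean(values)
  s <- if (n > 1) {
    if (sdType == "population") sqrt(mean((values - m)^2)) else stats::sd(values)
  } else 0
  dq <- propagateMeasurementError(rep(measErrorEach, n))
  list(n = n, mean = m, sd = s, measErrorEach = measErrorEach,
       propagatedError = dq, combined = sqrt(s^2 + dq^2))
}

#' Group ice-thickness statistics
#'
#' Aggregates hole-centre or hole-edge ice thickness over one grid family:
#' mean and SD over the minima of the recorded ranges (the survey figures
#' use minimum measured values), the propagated 5 nm-per-measurement
#' error, and their quadrature sum. Intentionally-thick preparations are
#' excluded by default.
#'
#' @param records survey data.frame from \code{\link{loadSurvey}}.
#' @param family grid family (see \code{\link{gridFamily}}).
#' @param location "center" or "edge".
#' @param rangeRule "min" (default), "mid" or "max".
#' @param excludeIntentionallyThick logical.
#' @param sdType "population" (divide by N) or "sample" (N - 1).
#' @param measError per-measurement error, nm.
#' @return list(n, mean, sd, measErrorEach, propagatedError, combined).
#' @export
groupIceStats <- function(records, family, location = c("center", "edge"),
                          rangeRule = c("min", "mid", "max"),
                          excludeIntentionallyThick = TRUE,
                          sdType = c("population", "sample"),
                          measError = 5) {
  location <- match.arg(location)
  rangeRule <- match.arg(rangeRule)
  sdType <- match.arg(sdType)
  sel <- records[!is.na(records$grid_family) &
                 records$grid_family == family, , drop = FALSE]
  if (excludeIntentionallyThick)
    sel <- sel[!isTRUE2(sel$intentionally_thick), , drop = FALSE]
  col <- if (location == "center") "t_center" else "t_edge"
  vals <- numeric(0)
  for (tok in sel[[col]]) {
    r <- parseRangeToken(tok)
    if (is.null(r)) next
    vals <- c(vals, switch(rangeRule, min = r[1], mid = mean(r), max = r[2]))
  }
  if (length(vals) == 0) stop("no ", location, " thickness values in family ",
                              family)
  .groupStat(vals, measError, sdType)
}

# vectorized isTRUE for logical columns that may contain NA
isTRUE2 <- function(x) !is.na(x) & x

#' Fractions of samples with single / double particle layers
#'
#' Counts layer tokens at a location: "1" and "1-2" count toward single
#' layers, "2" and "1-2" toward double (a sample whose holes vary counts
#' in both). Tokens such as "0 or 2" count toward each listed value. The
#' denominator is the number of samples with a countable token.
#'
#' @param records survey data.frame.
#' @param location "center", "edge" or "substrate".
#' @return list(single, double, nSingle, nDouble, nTotal), fractions in
#'   percent.
#' @export
groupLayerFractions <- function(records,
                                location = c("center", "edge", "substrate")) {
  location <- match.arg(location)
  col <- paste0("layers_", location)
  toks <- records[[col]]
  toks <- toks[!is.na(toks) & !toks %in% c("--", "", "uniform")]
  hasVal <- function(tok, v) {
    r <- parseRangeToken(tok)
    if (!is.null(r)) return(v >= r[1] && v <= r[2])
    vs <- suppressWarnings(as.numeric(strsplit(tok, " or ", fixed = TRUE)[[1]]))
    v %in% vs
  }
  nSingle <- sum(vapply(toks, hasVal, logical(1), v = 1))
  nDouble <- sum(vapply(toks, hasVal, logical(1), v = 2))
  n <- length(toks)
  list(single = 100 * nSingle / n, double = 100 * nDouble / n,
       nSingle = nSingle, nDouble = nDouble, nTotal = n)
}

#' Group particle-layer tilt statistics
#'
#' Aggregates the recorded layer tilts (degrees) at hole centres or edges
#' over both interfaces; recorded ranges contribute their midpoint and
#' every recorded alternative contributes. Per-measurement error is 1
#' degree.
#'
#' @param records survey data.frame.
#' @param location "center" or "edge".
#' @param sdType "population" or "sample".
#' @param measError degrees.
#' @return list(n, mean, sd, measErrorEach, propagatedError, combined).
#' @export
groupTiltStats <- function(records, location = c("center", "edge"),
                           sdType = c("population", "sample"),
                           measError = 1) {
  location <- match.arg(location)
  sdType <- match.arg(sdType)
  cols <- paste0(c("tilt_bottom_", "tilt_top_"), location)
  vals <- numeric(0)
  for (col in cols)
    for (tok in records[[col]]) vals <- c(vals, .expandAngles(tok))
  if (!length(vals)) stop("no tilt entries at ", location)
  .groupStat(vals, measError, sdType)
}

#' Classify a sample as ideal / near-ideal / neither
#'
#' Near-ideal regions have under 100 nm ice (minimum centre thickness), a
#' layer token admitting a single non-overlapping layer (minimum layer
#' count at the centre at most 1), and little or no apparent preferred
#' orientation ("no" or "some"). Ideal additionally requires evidence of
#' no particle-air-water-interface interaction. Missing fields give
#' "indeterminate".
#'
#' @param record one survey row (data.frame of one row or list).
#' @return "ideal", "near_ideal", "neither" or "indeterminate".
#' @export
classifyConditions <- function(record) {
  tok <- record$t_center
  lay <- record$layers_center
  ori <- record$preferred_orientation
  if (is.null(tok) || is.na(tok) || tok == "--" ||
      is.null(lay) || is.na(lay) || lay == "--" ||
      is.null(ori) || is.na(ori) || ori == "unknown")
    return("indeterminate")
  r <- parseRangeToken(tok)
  if (is.null(r)) return("indeterminate")
  thin <- r[1] < 100
  minLayers <- if (lay == "uniform") NA_real_ else {
    rr <- parseRangeToken(lay)
    if (!is.null(rr)) rr[1]
    else min(suppressWarnings(
      as.numeric(strsplit(lay, " or ", fixed = TRUE)[[1]])))
  }
  if (is.na(minLayers)) return("indeterminate")
  nearIdeal <- thin && minLayers <= 1 && ori %in% c("no", "some")
  if (!nearIdeal) return("neither")
  if (identical(record$no_awi_interaction, "yes")) "ideal" else "near_ideal"
}
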