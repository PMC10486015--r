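# Paired-site statistics on per-sample metric tables. A metric table has one
# row per sample with columns `sample_id`, `patient_id`, `site` ("AB" or
# "FB") plus numeric metric columns; patients pair exactly one AB with one FB
# sample.

check_metric_table <- function(table, metric = NULL) {
  need <- c("sample_id", "patient_id", "site")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop(sprintf("metric table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!all(table$site %in% c("AB", "FB")))
    stop("`site` must be 'AB' or 'FB'", call. = FALSE)
  if (!is.null(metric) && !metric %in% names(table))
    stop(sprintf("metric column '%s' not found", metric), call. = FALSE)
  invisible(table)
}

paired_values <- function(table, metric) {
  check_metric_table(table, metric)
  ab <- table[table$site == "AB", c("patient_id", metric)]
  fb <- table[table$site == "FB", c("patient_id", metric)]
  common <- intersect(ab$patient_id, fb$patient_id)
  orphans <- setdiff(union(ab$patient_id, fb$patient_id), common)
  if (length(orphans))
    stop(sprintf("unpaired sample(s) for patient(s): %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  list(ab = ab[[metric]][match(common, ab$patient_id)],
       fb = fb[[metric]][match(common, fb$patient_id)],
       patients = common)
}

#' Per-site mean, minimum and maximum of a metric
#'
#' @param table a per-sample metric table (see package vignette); columns
#'   `sample_id`, `patient_id`, `site` plus metrics.
#' @param metric metric column name.
#' @return data frame with one row per site: `site`, `n`, `mean`, `min`,
#'   `max`.
#' @export
group_summary <- function(table, metric) {
  check_metric_table(table, metric)
  x <- table[[metric]]
  keep <- !is.na(x)
  sites <- c("AB", "FB")
  rows <- lapply(sites, function(s) {
    v <- x[keep & table$site == s]
    if (!length(v))
      stop(sprintf("no values for site %s", s), call. = FALSE)
    data.frame(site = s, n = length(v), mean = mean(v), min = min(v),
               max = max(v))
  })
  do.call(rbind, rows)
}

#' Paired two-sample t test
#'
#' Classical paired t on per-patient differences: `t = mean(d) /
#' (sd(d) / sqrt(n))` with the sample SD, `df = n - 1`, two-sided p from the
#' central t distribution.
#'
#' @param x,y numeric vectors paired by position (same patient order).
#' @return list with `t`, `df`, `p`, `n`, `mean_difference`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must pair up", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (sd(d) == 0)
    stop("degenerate paired test: differences have zero variance",
         call. = FALSE)
  ht <- t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, n = length(x), mean_difference = mean(d))
}

#' Unpaired two-sample t test
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @param variance `"pooled"` (classical equal-variance t,
#'   `df = n1 + n2 - 2`) or `"welch"` (Welch-Satterthwaite df).
#' @return list with `t`, `df`, `p`.
#' @export
unpaired_t_test <- function(x, y, variance = c("pooled", "welch")) {
  variance <- match.arg(variance)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  if (variance == "pooled" && sd(c(x - mean(x), y - mean(y))) == 0)
    stop("degenerate test: zero pooled variance", call. = FALSE)
  ht <- t.test(x, y, var.equal = (variance == "pooled"))
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Build the standard result tables from per-sample metric tables
#'
#' Reassembles, from a per-sample metric table, the result tables of a
#' paired recipient/donor (AB/FB) bone comparison: per-metric site means
#' with paired and unpaired t-test p-values, the cross-resolution lacunar
#' density ratios, the orientation LOA table with FB/AB ratios, and the
#' permeability anisotropy table. Only the blocks whose input columns are
#' present are built.
#'
#' @param table per-sample metric table; metric columns are all numeric
#'   columns except the id columns. Special columns: `density_low_res` and
#'   `density_high_res` (per mm^3) trigger the resolution-ratio table;
#'   `s_phi` and `s_theta` trigger the LOA table; `ratio_EV_mean` triggers
#'   the permeability table.
#' @param paired compute paired p-values (requires complete pairing).
#' @return list of data frames: `summary` (site means/min/max + p-values per
#'   metric), `per_sample`, and optionally `resolution`, `orientation`,
#'   `permeability`.
#' @export
build_paper_tables <- function(table, paired = TRUE) {
  check_metric_table(table)
  if (!nrow(table)) stop("empty metric table", call. = FALSE)
  idcols <- c("sample_id", "patient_id", "site")
  metrics <- setdiff(names(table)[vapply(table, is.numeric, TRUE)], idcols)
  special <- c("density_low_res", "density_high_res", "s_phi", "s_theta",
               "ratio_EV_mean")
  plain <- setdiff(metrics, special)

  summary_rows <- lapply(plain, function(mname) {
    gs <- tryCatch(group_summary(table, mname), error = function(e) NULL)
    if (is.null(gs)) return(NULL)             # metric absent for one site
    p_unpaired <- tryCatch(
      unpaired_t_test(table[[mname]][table$site == "AB"],
                      table[[mname]][table$site == "FB"])$p,
      error = function(e) NA_real_)
    p_paired <- NA_real_
    if (paired) {
      p_paired <- tryCatch({
        pv <- paired_values(table, mname)
        paired_t_test(pv$ab, pv$fb)$p
      }, error = function(e) NA_real_)
    }
    data.frame(metric = mname,
               mean_AB = gs$mean[gs$site == "AB"],
               min_AB = gs$min[gs$site == "AB"],
               max_AB = gs$max[gs$site == "AB"],
               mean_FB = gs$mean[gs$site == "FB"],
               min_FB = gs$min[gs$site == "FB"],
               max_FB = gs$max[gs$site == "FB"],
               p_unpaired = p_unpaired, p_paired = p_paired)
  })
  out <- list(per_sample = table,
              summary = do.call(rbind, summary_rows))

  if (all(c("density_low_res", "density_high_res") %in% names(table))) {
    keep <- !is.na(table$density_low_res) & !is.na(table$density_high_res)
    out$resolution <- data.frame(
      sample_id = table$sample_id[keep],
      density_low_res = table$density_low_res[keep],
      density_high_res = table$density_high_res[keep],
      ratio = density_resolution_ratio(table$density_high_res[keep],
                                       table$density_low_res[keep]))
  }

  if (all(c("s_phi", "s_theta") %in% names(table))) {
    loa <- table$s_phi * table$s_theta
    orient <- data.frame(sample_id = table$sample_id,
                         patient_id = table$patient_id, site = table$site,
                         s_phi = table$s_phi, s_theta = table$s_theta,
                         LOA = loa, loa_ratio_fb_ab = NA_real_)
    for (pid in unique(orient$patient_id)) {
      iab <- which(orient$patient_id == pid & orient$site == "AB")
      ifb <- which(orient$patient_id == pid & orient$site == "FB")
      if (length(iab) == 1 && length(ifb) == 1 && orient$LOA[iab] > 0)
        orient$loa_ratio_fb_ab[iab] <-
          loa_ratio(orient$LOA[ifb], orient$LOA[iab])
    }
    out$orientation <- orient
  }

  if ("ratio_EV_mean" %in% names(table)) {
    r <- table$ratio_EV_mean
    out$permeability <- data.frame(
      sample_id = table$sample_id, site = table$site,
      ratio_EV_mean = r, invert = ifelse(!is.na(r) & r > 0, 1 / r, NA_real_))
  }
  out
}
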