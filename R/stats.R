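# Group-level quantification: per-section liver metrics, cohort summaries,
# pairwise significance tests and report files.

#' Mean speed of sound within the liver mask
#'
#' @param sos_image a [recon_image()] with `mode = "sos"` (or any image in
#'   m/s).
#' @param liver_mask logical matrix, non-empty.
#' @return mean of the masked pixels (m/s).
#' @export
liver_mean_sos <- function(sos_image, liver_mask) {
  stopifnot(inherits(sos_image, "recon_image"))
  if (!any(liver_mask)) stop("empty liver mask", call. = FALSE)
  mean(sos_image$pixels[liver_mask])
}

#' Assemble a cohort table
#'
#' Standard per-section table consumed by the statistics layer.
#'
#' @param section_id unique section identifiers.
#' @param group group labels.
#' @param mouse_id animal identifiers.
#' @param liver_mean_sos m/s per section.
#' @param lipid_metric a.u. per section.
#' @param area mm^2 per section.
#' @param weight g per section.
#' @param qc_excluded logical exclusion flag.
#' @return data.frame of class `cohort_table`.
#' @export
cohort_table <- function(section_id, group, mouse_id = section_id,
                         liver_mean_sos = NA_real_, lipid_metric = NA_real_,
                         area = NA_real_, weight = NA_real_,
                         qc_excluded = FALSE) {
  if (anyDuplicated(section_id))
    stop("duplicate section_ids", call. = FALSE)
  out <- data.frame(section_id = section_id, group = group,
                    mouse_id = mouse_id, liver_mean_sos = liver_mean_sos,
                    lipid_metric = lipid_metric, area = area,
                    weight = weight, qc_excluded = qc_excluded,
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Per-group mean, standard deviation and count
#'
#' Sample mean and sample SD (n-1 denominator) of one metric per group,
#' excluding QC-flagged rows.
#'
#' @param table a [cohort_table()] (or compatible data.frame).
#' @param metric column name, e.g. `"liver_mean_sos"`.
#' @return data.frame with columns `group`, `mean`, `sd`, `n`.
#' @export
group_summary <- function(table, metric) {
  stopifnot(metric %in% names(table))
  tab <- table[!(table$qc_excluded %in% TRUE), , drop = FALSE]
  out <- do.call(rbind, lapply(split(tab[[metric]], tab$group), function(v) {
    data.frame(mean = mean(v), sd = sd(v), n = length(v))
  }))
  out <- data.frame(group = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  small <- out$group[out$n < 2]
  if (length(small))
    stop("group(s) with fewer than 2 sections: ",
         paste(small, collapse = ", "), call. = FALSE)
  out
}

#' Unpaired two-sample t-test
#'
#' Student's pooled-variance two-sample t-test (two-tailed) by default;
#' `welch = TRUE` switches to the Welch variant.  When both groups have
#' zero variance and equal means, `t = 0, p = 1` by convention.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param welch use the Welch (unequal-variance) t-test.
#' @return list with `t`, `p`, `df`, `stars`.
#' @export
unpaired_ttest <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("both groups need at least 2 values", call. = FALSE)
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2,
                  stars = significance_stars(1)))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0,
                df = length(a) + length(b) - 2,
                stars = significance_stars(0)))
  }
  ht <- t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), stars = significance_stars(ht$p.value))
}

#' Significance star mapping
#'
#' `p <= 0.05` "*", `<= 0.01` "**", `<= 0.001` "***", `<= 0.0001` "****";
#' otherwise "ns".
#'
#' @param p p-value.
#' @return character.
#' @export
significance_stars <- function(p) {
  if (p <= 0.0001) "****" else if (p <= 0.001) "***"
  else if (p <= 0.01) "**" else if (p <= 0.05) "*" else "ns"
}

#' Percent difference relative to a reference mean
#'
#' `100 * (meanA - meanB) / meanB`.
#'
#' @param meanA group mean of interest.
#' @param meanB reference group mean (non-zero).
#' @return percent difference.
#' @export
percent_difference <- function(meanA, meanB) {
  if (meanB == 0) stop("reference mean is zero", call. = FALSE)
  100 * (meanA - meanB) / meanB
}

#' Cohort report files
#'
#' Writes, per metric (speed of sound, lipid, area, weight): group
#' summaries and all pairwise Student t-tests as CSV; plus a long-format
#' boxplot-ready CSV and a JSON manifest (groups, n, exclusions, seed).
#'
#' @param table a [cohort_table()].
#' @param out_dir output directory (created if needed).
#' @param seed seed recorded in the manifest.
#' @return invisibly, the list of written file paths.
#' @export
build_report <- function(table, out_dir, seed = NA) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- c("liver_mean_sos", "lipid_metric", "area", "weight")
  metrics <- metrics[vapply(metrics, function(m)
    any(is.finite(table[[m]])), logical(1))]
  used <- table[!(table$qc_excluded %in% TRUE), , drop = FALSE]
  files <- character(0)
  summaries <- list(); tests <- list()
  for (m in metrics) {
    gs <- group_summary(used, m)
    gs$metric <- m
    summaries[[m]] <- gs
    grp <- unique(used$group)
    if (length(grp) >= 2) {
      cmb <- utils::combn(grp, 2)
      tests[[m]] <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
        a <- used[[m]][used$group == cmb[1, k]]
        b <- used[[m]][used$group == cmb[2, k]]
        tt <- unpaired_ttest(a, b)
        data.frame(metric = m, group_a = cmb[1, k], group_b = cmb[2, k],
                   t = tt$t, p = tt$p, stars = tt$stars,
                   percent_difference = percent_difference(mean(a), mean(b)),
                   stringsAsFactors = FALSE)
      }))
    }
  }
  f <- file.path(out_dir, "group_summaries.csv")
  write.csv(do.call(rbind, summaries), f, row.names = FALSE)
  files <- c(files, f)
  if (length(tests)) {
    f <- file.path(out_dir, "pairwise_tests.csv")
    write.csv(do.call(rbind, tests), f, row.names = FALSE)
    files <- c(files, f)
  }
  long <- do.call(rbind, lapply(metrics, function(m)
    data.frame(section_id = used$section_id, group = used$group,
               metric = m, value = used[[m]], stringsAsFactors = FALSE)))
  f <- file.path(out_dir, "cohort_long.csv")
  write.csv(long, f, row.names = FALSE)
  files <- c(files, f)
  manifest <- list(
    groups = as.list(table(used$group)), seed = seed,
    n_sections = nrow(table),
    excluded = table$section_id[table$qc_excluded %in% TRUE]
  )
  f <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}
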