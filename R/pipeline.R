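# End-to-end orchestration: standardize -> segment -> clean -> split ->
# corners -> measure -> classify, plus the evaluation workflows.

#' Pipeline configuration
#'
#' One place for every stage's tunables and seeds, so a run can be
#' reproduced bit-identically from its provenance record.
#'
#' @param backend segmentation backend ("oracle" or "model")
#' @param min_area_mm2,max_dist_mm mask post-processing thresholds
#' @param corner_seed,corner_iterations basin-hopping controls
#' @param central_fraction chord fraction for the central height
#' @param assess_labels vertebrae passed to fracture assessment
#' @param labels optional explicit cranial-to-caudal label vector
#' @param sacrum_present label inference switch when `labels` is NULL
#' @param corruption optional [mask_corruption()] for the oracle backend
#' @param corruption_seed seed of the corruption model
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(backend = "oracle",
                            min_area_mm2 = 50, max_dist_mm = 40,
                            corner_seed = 0L, corner_iterations = 50L,
                            central_fraction = 0.5,
                            assess_labels = c("L1", "L2", "L3", "L4", "L5"),
                            labels = NULL, sacrum_present = TRUE,
                            corruption = NULL, corruption_seed = 0L) {
  structure(
    list(backend = backend, min_area_mm2 = min_area_mm2,
         max_dist_mm = max_dist_mm, corner_seed = as.integer(corner_seed),
         corner_iterations = as.integer(corner_iterations),
         central_fraction = central_fraction, assess_labels = assess_labels,
         labels = labels, sacrum_present = sacrum_present,
         corruption = corruption,
         corruption_seed = as.integer(corruption_seed)),
    class = "pipeline_config"
  )
}

config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

load_image_input <- function(input) {
  if (is.character(input)) {
    if (!file.exists(input)) stop("unreadable input: ", input)
    nii <- read_nifti(input)
    list(data = nii$data, spacing = nii$spacing)
  } else if (is.matrix(input) || is.array(input)) {
    sp <- attr(input, "spacing_mm")
    if (is.null(sp)) stop("in-memory input needs a spacing_mm attribute")
    list(data = input, spacing = rep_len(sp, 2))
  } else stop("input must be a NIfTI path or a matrix/array")
}

#' Run the full measurement pipeline on one case
#'
#' Executes slice selection (for volumes), standardization, segmentation,
#' mask post-processing, vertebra splitting/labelling, corner detection by
#' all three strategies with the overlap selector, morphometry, and
#' Genant-rule classification of the configured vertebral levels.
#'
#' @param input NIfTI path (2-D slice or 3-D sagittal stack) or numeric
#'   matrix/array with a `spacing_mm` attribute
#' @param norms a [reference_norms()] object (required for classification)
#' @param config a [pipeline_config()]
#' @param labels_input ground-truth label mask (path or matrix) for the
#'   oracle backend
#' @param model trained [build_unet()] model for the model backend
#' @param case_id identifier carried into the report
#' @param out_dir if given, writes `measurements.csv` and `report.json`
#' @return `case_report`: list with `case_id`, `vertebrae` (one row per
#'   vertebra: label, corner strategy and overlap, corner coordinates,
#'   AH/PH/CH/SC/IC/VA, deformity, fractured) and `provenance`
#' @export
run_measure <- function(input, norms, config = pipeline_config(),
                        labels_input = NULL, model = NULL,
                        case_id = "case", out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  img <- load_image_input(input)
  vol <- img$data
  if (length(dim(vol)) == 3L && dim(vol)[3] > 1L) {
    ci <- select_center_slice(dim(vol)[3])
    slice <- vol[, , ci + 1L]
  } else if (length(dim(vol)) == 3L) {
    slice <- vol[, , 1L]
  } else slice <- vol
  std <- standardize_slice(slice, img$spacing[1:2])

  lab_std <- NULL
  if (!is.null(labels_input)) {
    lab <- load_image_input(labels_input)
    lv <- lab$data
    if (length(dim(lv)) == 3L) {
      lv <- lv[, , select_center_slice(dim(lv)[3]) + 1L]
    }
    lab_std <- standardize_slice(lv, lab$spacing[1:2], label_mask = TRUE)
  }

  mask <- segment_slice(std, backend = config$backend, labels = lab_std,
                        corruption = config$corruption,
                        seed = config$corruption_seed, model = model)
  cleaned <- clean_mask(mask, min_area_mm2 = config$min_area_mm2,
                        max_dist_mm = config$max_dist_mm)
  comps <- split_and_label(cleaned, labels = config$labels,
                           sacrum_present = config$sacrum_present)
  if (length(comps) == 0L) stop("no vertebral components after post-processing")

  quads <- lapply(comps, detect_corners, seed = config$corner_seed,
                  iterations = config$corner_iterations)
  morphs <- Map(function(comp, quad) {
    measure_vertebra(comp$mask, quad,
                     central_fraction = config$central_fraction)
  }, comps, quads)

  n <- length(comps)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    lbl <- comps[[i]]$label
    m <- morphs[[i]]
    assess <- lbl %in% config$assess_labels
    deform <- NA_character_; fractured <- NA
    if (assess) {
      nb <- morphs[setdiff(c(i - 1L, i + 1L), c(0L, n + 1L))]
      fc <- classify_vertebra(m, neighbors = nb, norms = norms, label = lbl)
      deform <- fc$deformity; fractured <- fc$fractured
    }
    co <- quads[[i]]$corners
    rows[[i]] <- data.frame(
      label = lbl, strategy = quads[[i]]$strategy,
      overlap = quads[[i]]$overlap,
      as_x = co["as", 1], as_y = co["as", 2],
      ps_x = co["ps", 1], ps_y = co["ps", 2],
      pi_x = co["pi", 1], pi_y = co["pi", 2],
      ai_x = co["ai", 1], ai_y = co["ai", 2],
      AH = m$AH, PH = m$PH, CH = m$CH, SC = m$SC, IC = m$IC, VA = m$VA,
      deformity = deform, fractured = fractured,
      stringsAsFactors = FALSE
    )
  }
  vertebrae <- do.call(rbind, rows)
  report <- structure(
    list(
      case_id = case_id,
      vertebrae = vertebrae,
      provenance = list(
        package_version = as.character(utils::packageVersion("vertmorph")),
        backend = config$backend,
        corner_seed = config$corner_seed,
        corner_iterations = config$corner_iterations,
        corruption_seed = config$corruption_seed,
        config_hash = config_hash(config)
      )
    ),
    class = "case_report"
  )
  if (!is.null(out_dir)) write_case_report(report, out_dir)
  report
}

#' @export
print.case_report <- function(x, ...) {
  cat("Case", x$case_id, "-", nrow(x$vertebrae), "vertebrae\n")
  v <- x$vertebrae
  for (i in seq_len(nrow(v))) {
    cat(sprintf(" %-4s AH %5.1f PH %5.1f CH %5.1f SC %4.1f IC %4.1f VA %6.1f  %s\n",
                v$label[i], v$AH[i], v$PH[i], v$CH[i], v$SC[i], v$IC[i],
                v$VA[i],
                if (is.na(v$fractured[i])) "(not assessed)"
                else if (v$fractured[i]) paste0("FRACTURE: ", v$deformity[i])
                else "intact"))
  }
  invisible(x)
}

#' Write a case report as CSV + JSON
#' @param report a `case_report`
#' @param dir output directory
#' @return invisibly, the file paths
#' @export
write_case_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "measurements.csv")
  js <- file.path(dir, "report.json")
  utils::write.csv(report$vertebrae, csv, row.names = FALSE)
  jsonlite::write_json(
    list(case_id = report$case_id,
         vertebrae = report$vertebrae,
         provenance = report$provenance),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = csv, json = js))
}

#' Evaluate predicted fracture calls against a reference standard
#'
#' Builds per-stratum contingency counts and diagnostic metrics, mirroring
#' the usual validation-table layout (one row per stratum, three metrics
#' with CIs). The overall row ("all") is always included.
#'
#' @param calls data frame with logical/0-1 columns `predicted` and
#'   `reference`, plus any stratum columns
#' @param strata character vector of stratum column names (each value of
#'   each column becomes a row); empty for the overall row only
#' @param method CI method, see [diagnostic_metrics()]
#' @return list with `counts` (stratum, tp, fp, tn, fn, n) and `metrics`
#'   (stratum, metric, estimate, lower, upper)
#' @export
run_evaluate <- function(calls, strata = character(),
                         method = "clopper-pearson") {
  need <- c("predicted", "reference")
  if (!all(need %in% names(calls))) {
    stop("calls need columns: ", paste(need, collapse = ", "))
  }
  miss <- setdiff(strata, names(calls))
  if (length(miss) > 0) stop("unknown stratum columns: ",
                             paste(miss, collapse = ", "))
  pred <- as.logical(calls$predicted)
  ref <- as.logical(calls$reference)
  if (anyNA(pred) || anyNA(ref)) stop("predicted/reference contain NA")

  groups <- list(list(stratum = "all", rows = seq_len(nrow(calls))))
  for (scol in strata) {
    for (v in unique(calls[[scol]])) {
      rows <- which(calls[[scol]] == v)
      if (length(rows) == 0) next
      groups[[length(groups) + 1L]] <-
        list(stratum = paste0(scol, ":", v), rows = rows)
    }
  }
  counts <- list(); metrics <- list()
  for (g in groups) {
    p <- pred[g$rows]; r <- ref[g$rows]
    cc <- contingency_counts(sum(p & r), sum(p & !r), sum(!p & !r),
                             sum(!p & r), stratum = g$stratum)
    counts[[length(counts) + 1L]] <- data.frame(
      stratum = g$stratum, tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
      n = cc$total)
    dm <- diagnostic_metrics(cc, method = method)
    dm$stratum <- g$stratum
    metrics[[length(metrics) + 1L]] <- dm[, c("stratum", "metric", "estimate",
                                              "lower", "upper")]
  }
  list(counts = do.call(rbind, counts), metrics = do.call(rbind, metrics))
}

#' Agreement statistics from a ratings table
#'
#' @param ratings data frame: one row per vertebra, one column per rater
#'   (plus optional id columns, ignored via `rater_cols`)
#' @param rater_cols names of the two (or more, for the ICC) rater columns
#' @param kind "icc", "kappa" or "bland-altman"
#' @param ... passed to the underlying statistic
#' @return the corresponding statistic object
#' @export
run_agreement <- function(ratings, rater_cols,
                          kind = c("icc", "kappa", "bland-altman"), ...) {
  kind <- match.arg(kind)
  stopifnot(all(rater_cols %in% names(ratings)))
  x <- ratings[, rater_cols, drop = FALSE]
  switch(kind,
    icc = icc(x, ...),
    kappa = {
      stopifnot(length(rater_cols) == 2)
      cohens_kappa(x[[1]], x[[2]], ...)
    },
    `bland-altman` = {
      stopifnot(length(rater_cols) == 2)
      bland_altman(as.numeric(x[[1]]), as.numeric(x[[2]]))
    })
}

#' Classify a measurements table with supplied norms
#'
#' The file-level counterpart of [classify_vertebra()]: takes a
#' measurements CSV/data frame (label, AH, PH, CH in mm, rows ordered
#' cranial to caudal), applies the Genant rules per row using the adjacent
#' rows as neighbors, and returns the calls.
#'
#' @param measurements data frame or CSV path
#' @param norms a [reference_norms()] object
#' @param assess_labels which labels receive a call (default L1-L5)
#' @return data frame: label, deformity, fractured
#' @export
classify_measurements <- function(measurements, norms,
                                  assess_labels = c("L1", "L2", "L3", "L4", "L5")) {
  if (is.character(measurements)) {
    measurements <- utils::read.csv(measurements, stringsAsFactors = FALSE)
  }
  need <- c("label", "AH", "PH", "CH")
  if (!all(need %in% names(measurements))) {
    stop("measurements need columns: ", paste(need, collapse = ", "))
  }
  n <- nrow(measurements)
  as_m <- function(i) list(AH = measurements$AH[i], PH = measurements$PH[i],
                           CH = measurements$CH[i])
  out <- vector("list", n)
  for (i in seq_len(n)) {
    lbl <- measurements$label[i]
    if (!lbl %in% assess_labels) {
      out[[i]] <- data.frame(label = lbl, deformity = NA_character_,
                             fractured = NA)
      next
    }
    nb <- lapply(setdiff(c(i - 1L, i + 1L), c(0L, n + 1L)), as_m)
    fc <- classify_vertebra(as_m(i), neighbors = nb, norms = norms,
                            label = lbl)
    out[[i]] <- data.frame(label = lbl, deformity = fc$deformity,
                           fractured = fc$fractured)
  }
  do.call(rbind, out)
}
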