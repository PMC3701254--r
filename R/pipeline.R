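#' Batch run configuration
#'
#' Collects everything a reproducible batch run needs: the input stack, how
#' to segment it (label stacks pass through [extract_labels()]; gray stacks
#' need a `threshold`), the deformation parameters, and the output layout.
#' Outputs are always in nm.
#'
#' @param input path to a label or gray stack (NRRD or TIFF).
#' @param out_dir output directory (created if missing).
#' @param spacing optional nm spacing override for files without metadata.
#' @param labels optional integer vector restricting which labels to process
#'   (default: all).
#' @param params a [deform_params()].
#' @param threshold gray threshold; when given the input is treated as a
#'   gray stack and segmented with [threshold_segment()].
#' @param blur_sigma,min_size segmentation options, see [threshold_segment()].
#' @param mesh_format `"ply"` or `"obj"`.
#' @param fail_fast stop at the first per-junction failure instead of
#'   logging and continuing.
#' @param log_level `"info"` (one line per stage per junction) or `"quiet"`.
#' @return A `run_config` list.
#' @export
run_config <- function(input, out_dir, spacing = NULL, labels = NULL,
                       params = deform_params(), threshold = NULL,
                       blur_sigma = NULL, min_size = 50L,
                       mesh_format = c("ply", "obj"), fail_fast = FALSE,
                       log_level = c("info", "quiet")) {
  structure(list(input = input, out_dir = out_dir, spacing = spacing,
                 labels = labels, params = params, threshold = threshold,
                 blur_sigma = blur_sigma, min_size = min_size,
                 mesh_format = match.arg(mesh_format),
                 fail_fast = isTRUE(fail_fast),
                 log_level = match.arg(log_level)),
            class = "run_config")
}

#' Batch SAS extraction
#'
#' Runs [extract_sas()] plus full [morphometry()] on every junction of a
#' stack, writing one mesh per junction, a feature-table CSV
#' (`features.csv`) and a JSON run summary (`summary.json` with processed /
#' converged / failed counts, per-stage timings and a parameter echo).
#' Non-converged junctions are flagged in the table, not dropped; per-junction
#' failures are logged and counted, and the run continues unless
#' `fail_fast`. Outputs are deterministic for identical inputs and
#' configuration (timestamps are confined to the summary JSON).
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `features` (tibble) and `summary` (list).
#' @export
run_batch <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) {
    if (config$log_level == "info") message(...)
  }
  t0 <- proc.time()[["elapsed"]]
  grid <- read_volume(config$input, spacing_override = config$spacing)
  masks <- if (!is.null(config$threshold)) {
    threshold_segment(grid, config$threshold, config$blur_sigma,
                      config$min_size)
  } else {
    extract_labels(grid)
  }
  if (!is.null(config$labels))
    masks <- Filter(function(m) m$label_id %in% config$labels, masks)
  if (length(masks) == 0L)
    warning("no junctions found in ", config$input)

  records <- list()
  failures <- list()
  timings <- numeric(0)
  for (m in masks) {
    log_msg("junction ", m$label_id, ": extract_sas (obb, distance map, ",
            "smoothing, seed, template, deform, clip)")
    tj <- proc.time()[["elapsed"]]
    res <- tryCatch({
      r <- extract_sas(m, config$params)
      log_msg("junction ", m$label_id, ": morphometry")
      rec <- morphometry(r, m)
      mesh_path <- file.path(config$out_dir,
                             sprintf("sas_label_%03d.%s", m$label_id,
                                     config$mesh_format))
      log_msg("junction ", m$label_id, ": write_mesh -> ",
              basename(mesh_path))
      write_mesh(r$sas, mesh_path, config$mesh_format)
      rec
    }, error = function(e) e)
    timings <- c(timings, proc.time()[["elapsed"]] - tj)
    if (inherits(res, "error")) {
      if (config$fail_fast) stop(res)
      warning("junction ", m$label_id, " failed: ", conditionMessage(res))
      failures[[length(failures) + 1L]] <-
        list(label_id = m$label_id, error = conditionMessage(res))
    } else {
      records[[length(records) + 1L]] <- res
    }
  }
  features <- if (length(records)) do.call(rbind, records) else
    tibble::tibble()
  write_feature_table(records, file.path(config$out_dir, "features.csv"))
  summary <- list(
    processed = length(masks),
    succeeded = length(records),
    converged = if (length(records)) sum(features$converged) else 0L,
    failed = length(failures),
    failures = failures,
    per_junction_seconds = round(timings, 3),
    total_seconds = round(proc.time()[["elapsed"]] - t0, 3),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = unclass(config$params),
    input = config$input)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(features = features, summary = summary))
}

#' Phantom self-test of the full pipeline
#'
#' Generates the standard phantom suite (flat slab at instrument spacing,
#' spherical shell sectors of increasing opening, perforated sheets with 1
#' and 3 holes), runs the complete extraction with the given parameters and
#' checks the analytic expectations: mid-plane recovery and area on the
#' slab, mean curvature and radial residual on the shell, boundary-loop
#' counts on the perforated sheets, area-ratio values and ordering, and
#' convergence everywhere.
#'
#' @param params a [deform_params()]; the defaults are the recommended
#'   operating point.
#' @param quiet suppress the printed check table.
#' @return Invisibly, a tibble of checks (`check`, `value`, `expected`,
#'   `pass`); attribute `"pass"` is `TRUE` when all checks pass.
#' @export
selftest <- function(params = deform_params(), quiet = FALSE) {
  checks <- list()
  add <- function(check, value, expected, pass) {
    checks[[length(checks) + 1L]] <<- tibble::tibble(
      check = check, value = value, expected = expected, pass = pass)
  }

  # flat slab at FIB/SEM instrument spacing
  slab <- make_phantom(phantom_spec("slab", size = c(740, 370, 60),
                                    spacing = c(3.7, 3.7, 20)))
  r <- tryCatch(extract_sas(slab$mask, params), error = function(e) e)
  if (inherits(r, "error")) {
    add("slab: pipeline runs", 0, 1, FALSE)
  } else {
    add("slab: converged", as.numeric(r$deform$converged), 1,
        r$deform$converged)
    resid <- max(abs(slab$truth$midsurface_point_test(r$sas$vertices)))
    add("slab: max mid-plane residual (nm) <= 10", resid, 10, resid <= 10)
    area <- surface_area(r$sas)
    add("slab: area within 5% of analytic", area / slab$truth$midsurface_area,
        1, abs(area / slab$truth$midsurface_area - 1) <= 0.05)
    ar <- area_ratio(r$sas, r$obb)
    add("slab: AR rounds to 0.00", round(ar, 2), 0, round(ar, 2) == 0)
  }

  # shell sectors, near-isotropic sampling; AR must grow with opening angle
  ars <- c()
  for (ha in c(15, 45, 75)) {
    sh <- make_phantom(phantom_spec("shell_sector", radius = 250,
                                    thickness = 40, half_angle = ha,
                                    spacing = c(4, 4, 4)))
    rs <- tryCatch(extract_sas(sh$mask, params), error = function(e) e)
    if (inherits(rs, "error")) {
      add(sprintf("shell %d deg: pipeline runs", ha), 0, 1, FALSE)
      next
    }
    add(sprintf("shell %d deg: converged", ha),
        as.numeric(rs$deform$converged), 1, rs$deform$converged)
    ars <- c(ars, area_ratio(rs$sas, rs$obb))
    if (ha == 45) {
      # evaluate curvature/residual over the cap proper: vertices whose
      # in-plane radius keeps the vertical chord inside the full shell
      # thickness (beyond it the medial surface tracks the sector's cut rim,
      # not the sphere)
      cf <- vertex_curvatures(rs$sas)
      rho <- sqrt(rs$sas$vertices[, 1]^2 + rs$sas$vertices[, 2]^2)
      cap <- cf$interior_mask & rho <= (250 - 20) * sin(45 * pi / 180)
      mH <- mean(abs(cf$H[cap]))
      add("shell 45 deg: cap mean |H| within 10% of 1/R", mH * 250, 1,
          abs(mH - 1 / 250) <= 0.1 / 250)
      resid <- mean(abs(sh$truth$midsurface_point_test(
        rs$sas$vertices[cap, , drop = FALSE])))
      add("shell 45 deg: cap mean radial residual < voxel pitch", resid, 4,
          resid < 4)
    }
  }
  if (length(ars) == 3L)
    add("shell AR strictly increasing over 15/45/75 deg",
        as.numeric(all(diff(ars) > 0)), 1, all(diff(ars) > 0))

  # full sphere: the mid-surface normal to the template is the equatorial disc
  sph <- make_phantom(phantom_spec("sphere", radius = 100, spacing = c(4, 4, 4)))
  rsph <- tryCatch(extract_sas(sph$mask, params), error = function(e) e)
  if (inherits(rsph, "error")) {
    add("sphere: pipeline runs", 0, 1, FALSE)
  } else {
    add("sphere: converged", as.numeric(rsph$deform$converged), 1,
        rsph$deform$converged)
    asp <- surface_area(rsph$sas)
    add("sphere: disc area within 15% of pi R^2", asp / (pi * 100^2), 1,
        abs(asp / (pi * 100^2) - 1) <= 0.15)
  }

  # perforated sheets: hole loops
  for (nh in c(1L, 3L)) {
    holes <- list(list(center = c(0, 0), radius = 50),
                  list(center = c(160, 120), radius = 40),
                  list(center = c(-150, -120), radius = 35))[seq_len(nh)]
    sheet <- make_perforated_sheet(
      phantom_spec("perforated_sheet", size = c(550, 480, 60), holes = holes,
                   spacing = c(3.7, 3.7, 20)))
    rp <- tryCatch(extract_sas(sheet$mask, params), error = function(e) e)
    if (inherits(rp, "error")) {
      add(sprintf("sheet %d hole(s): pipeline runs", nh), 0, 1, FALSE)
      next
    }
    loops <- boundary_loops(rp$sas)
    add(sprintf("sheet %d hole(s): boundary loops", nh), loops, nh + 1L,
        loops == nh + 1L)
    add(sprintf("sheet %d hole(s): converged", nh),
        as.numeric(rp$deform$converged), 1, rp$deform$converged)
  }

  tab <- do.call(rbind, checks)
  if (!quiet) {
    print(as.data.frame(tab), row.names = FALSE)
    cat(if (all(tab$pass)) "\nAll checks passed.\n" else
      "\nSOME CHECKS FAILED.\n")
  }
  attr(tab, "pass") <- all(tab$pass)
  invisible(tab)
}
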