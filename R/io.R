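# File I/O: NIfTI volumes and masks, JSON contours / spec / sidecars,
# report writing and light schema validation.
#
# JSON contour convention (external interchange): per-slice polygon vertex
# lists in 0-based pixel coordinates with x = column and y = row. The
# in-memory convention is 1-based (R matrices); conversion happens here.

write_nifti_array <- function(arr, path, pixel_spacing, slice_thickness = NULL) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  pd <- if (nd >= 3L) c(pixel_spacing, pixel_spacing, slice_thickness) else
    rep(pixel_spacing, 2L)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

read_nifti_array <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))   # drop niftiImage bookkeeping
  arr[is.nan(arr)] <- NA_real_
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  arr
}

contours_to_json_list <- function(contours) {
  lapply(contours, function(ct) {
    list(epi = unname(cbind(ct$epi[, 1L] - 1, ct$epi[, 2L] - 1)),
         endo = unname(cbind(ct$endo[, 1L] - 1, ct$endo[, 2L] - 1)))
  })
}

json_list_to_contours <- function(lst) {
  conv <- function(m) {
    m <- as.matrix(m)
    colnames(m) <- c("x", "y")
    m + 1
  }
  # jsonlite simplification may yield either a per-slice list of
  # {epi, endo} objects or a columnar list of per-slice matrices
  if (!is.null(lst$epi)) {
    Map(function(e, en) list(epi = conv(e), endo = conv(en)), lst$epi, lst$endo)
  } else {
    lapply(lst, function(ct) list(epi = conv(ct$epi), endo = conv(ct$endo)))
  }
}

#' Write contours to JSON
#'
#' @param contours Per-slice list of `list(epi = , endo = )` vertex matrices
#'   (1-based pixel coordinates, columns `x`, `y`).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_contours_json <- function(contours, path) {
  jsonlite::write_json(list(slices = contours_to_json_list(contours)), path,
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read contours from JSON
#'
#' @param path File written by [write_contours_json()] (0-based x/y vertex
#'   lists).
#' @return Per-slice contour list in the in-memory (1-based) convention.
#' @export
read_contours_json <- function(path) {
  if (!file.exists(path)) stopf("read_contours_json: no such file: %s", path)
  json_list_to_contours(jsonlite::read_json(path, simplifyVector = TRUE)$slices)
}

#' Write a phantom to a directory
#'
#' Writes the LGE stack, truth masks, mid-slice ECV and T1 maps as NIfTI
#' (`.nii.gz`), and the contours, spec and T1 sidecar (blood T1 scalars,
#' hematocrit) as JSON. The set round-trips losslessly through
#' [read_phantom()] up to NIfTI single-precision storage of floating-point
#' maps (the LGE stack and masks round-trip bit-exactly as float64/int).
#'
#' @param out A `phantom_output` from [generate_phantom()].
#' @param directory Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_phantom <- function(out, directory) {
  if (!inherits(out, "phantom_output")) stopf("write_phantom: out must be a phantom_output")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stopf("write_phantom: cannot create directory %s", directory)
  sp <- out$lge$pixel_spacing
  th <- out$lge$slice_thickness
  paths <- c(
    lge = file.path(directory, "lge.nii.gz"),
    truth = file.path(directory, "truth_masks.nii.gz"),
    ecv = file.path(directory, "ecv.nii.gz"),
    t1_pre = file.path(directory, "t1_myo_pre.nii.gz"),
    t1_post = file.path(directory, "t1_myo_post.nii.gz"),
    contours = file.path(directory, "contours.json"),
    spec = file.path(directory, "spec.json"),
    sidecar = file.path(directory, "t1_blood.json")
  )
  write_nifti_array(out$lge$data, paths["lge"], sp, th)
  truth <- array(0L, dim = dim(out$lge$data))
  for (s in seq_along(out$truth_masks)) truth[, , s] <- out$truth_masks[[s]] * 1L
  write_nifti_array(truth, paths["truth"], sp, th)
  ecv <- out$ecv_specified$ecv
  ecv[!out$ecv_specified$valid_mask] <- NaN
  write_nifti_array(ecv, paths["ecv"], sp)
  write_nifti_array(out$t1pair$t1_myo_pre, paths["t1_pre"], sp)
  write_nifti_array(out$t1pair$t1_myo_post, paths["t1_post"], sp)
  write_contours_json(out$contours, paths["contours"])
  spec <- unclass(out$spec_echo)
  jsonlite::write_json(spec[!vapply(spec, is.null, logical(1))], paths["spec"],
                       digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(list(t1_blood_pre = out$t1pair$t1_blood_pre,
                            t1_blood_post = out$t1pair$t1_blood_post,
                            hematocrit = out$t1pair$hematocrit,
                            mid_slice = out$lge$mid_slice),
                       paths["sidecar"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' Read a phantom directory
#'
#' @param directory Directory written by [write_phantom()].
#' @return A list mirroring `phantom_output` (`lge`, `contours`, `t1pair`,
#'   `ecv_specified`, `truth_masks`, `truth_scar_percent`, `spec_echo`).
#' @export
read_phantom <- function(directory) {
  need <- file.path(directory, c("lge.nii.gz", "truth_masks.nii.gz", "ecv.nii.gz",
                                 "t1_myo_pre.nii.gz", "t1_myo_post.nii.gz",
                                 "contours.json", "spec.json", "t1_blood.json"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stopf("read_phantom: missing file(s): %s", paste(missing, collapse = ", "))
  }
  spec_json <- jsonlite::read_json(file.path(directory, "spec.json"),
                                   simplifyVector = TRUE)
  spec <- do.call(phantom_spec, spec_json[names(spec_json) %in%
                                            names(formals(phantom_spec))])
  side <- jsonlite::read_json(file.path(directory, "t1_blood.json"),
                              simplifyVector = TRUE)
  lge_arr <- read_nifti_array(file.path(directory, "lge.nii.gz"))
  pd <- attr(lge_arr, "pixdim")
  attr(lge_arr, "pixdim") <- NULL
  stack <- lge_stack(lge_arr, pd[1L], pd[3L], side$mid_slice)
  truth_arr <- read_nifti_array(file.path(directory, "truth_masks.nii.gz"))
  truth_masks <- lapply(seq_len(dim(truth_arr)[3]),
                        function(s) truth_arr[, , s] > 0.5)
  ecv <- read_nifti_array(file.path(directory, "ecv.nii.gz"))
  attr(ecv, "pixdim") <- NULL
  t1_pre <- read_nifti_array(file.path(directory, "t1_myo_pre.nii.gz"))
  t1_post <- read_nifti_array(file.path(directory, "t1_myo_post.nii.gz"))
  attr(t1_pre, "pixdim") <- attr(t1_post, "pixdim") <- NULL
  contours <- read_contours_json(file.path(directory, "contours.json"))
  ring <- ring_mask_from_contours(contours[[1L]]$epi, contours[[1L]]$endo,
                                  dim(ecv))
  myo <- myo_mask(rep(list(ring), length(truth_masks)), stack$pixel_spacing,
                  stack$slice_thickness)
  truth_pct <- scar_result(truth_masks, myo, density = 1.05)$scar_percent
  structure(list(
    lge = stack, contours = contours,
    t1pair = t1_pair(t1_pre, t1_post, side$t1_blood_pre, side$t1_blood_post,
                     side$hematocrit),
    ecv_specified = ecv_map(ecv, !is.na(ecv)),
    truth_masks = truth_masks, truth_scar_percent = truth_pct,
    spec_echo = spec
  ), class = "phantom_output")
}

#' Validate a report against the shipped JSON schema
#'
#' Structural check of required fields and primitive types against the
#' schema in `inst/schema/report.schema.json` (a lightweight in-package
#' validator; nesting is checked one level deep for object-typed fields).
#'
#' @param report A named list (a parsed report).
#' @param schema_path Path to the schema; defaults to the shipped one.
#' @return `TRUE` invisibly; missing or mistyped fields are an error.
#' @export
validate_report <- function(report,
                            schema_path = system.file("schema", "report.schema.json",
                                                      package = "ecvlge")) {
  schema <- jsonlite::read_json(schema_path, simplifyVector = FALSE)
  check <- function(obj, sch, where) {
    req <- unlist(sch$required %||% list())
    missing <- setdiff(req, names(obj))
    if (length(missing)) {
      stopf("validate_report: missing field(s) at %s: %s", where,
            paste(missing, collapse = ", "))
    }
    for (nm in intersect(names(sch$properties %||% list()), names(obj))) {
      ty <- sch$properties[[nm]]$type
      val <- obj[[nm]]
      ok <- switch(ty %||% "any",
        number = is.numeric(val) && length(val) == 1L,
        string = is.character(val) && length(val) == 1L,
        object = is.list(val),
        array = is.list(val) || is.vector(val),
        TRUE)
      if (!ok) stopf("validate_report: field %s at %s is not of type %s", nm, where, ty)
      if (identical(ty, "object") && !is.null(sch$properties[[nm]]$required)) {
        check(val, sch$properties[[nm]], paste0(where, "$", nm))
      }
    }
  }
  check(report, schema, "report")
  invisible(TRUE)
}
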