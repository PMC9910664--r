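# Task lists: the executable form of the segmentation protocol. A task list
# is an ordered sequence of step descriptors; each step has a registered
# operation name, named parameters, and an optional/enabled flag pair.

TASK_OPS <- c("threshold", "shrinkwrap", "reload", "bitwise", "despeckle",
              "morphology", "save_bitmaps", "analysis3d", "model3d",
              "comment")

#' Construct a task list
#'
#' @param steps list of steps, each a list with `name` (a registered
#'   operation), `params` (named list), `optional` and `enabled` logicals.
#' @param provenance free-text origin note.
#' @return A `TaskList`.
#' @seealso [load_task_list()], [save_task_list()], [pats_task_list()]
#' @export
task_list <- function(steps, provenance = "in-memory") {
  for (i in seq_along(steps)) {
    s <- steps[[i]]
    if (is.null(s$name) || !s$name %in% TASK_OPS)
      stop(sprintf("unresolvable step %d: unknown operation '%s'", i,
                   if (is.null(s$name)) "<missing>" else s$name))
    steps[[i]]$params <- if (is.null(s$params)) list() else s$params
    steps[[i]]$optional <- isTRUE(s$optional)
    steps[[i]]$enabled <- if (is.null(s$enabled)) !isTRUE(s$optional)
                          else isTRUE(s$enabled)
  }
  structure(list(steps = steps, provenance = provenance), class = "TaskList")
}

#' @export
print.TaskList <- function(x, ...) {
  cat(sprintf("<TaskList> %d steps (%s)\n", length(x$steps), x$provenance))
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    p <- paste(sprintf("%s=%s", names(s$params), unlist(s$params)),
               collapse = " ")
    cat(sprintf("  %2d%s %s %s\n", i, if (s$optional) "*" else " ",
                s$name, p))
  }
  invisible(x)
}

step <- function(name, ..., optional = FALSE, enabled = !optional) {
  list(name = name, params = list(...), optional = optional,
       enabled = enabled)
}

#' The default pulmonary air-and-tissue segmentation parameters
#'
#' Defaults are the published protocol values for 8-bit reconstructions:
#' body/tissue threshold 55--255, air threshold 0--55, shrink-wrap bridging
#' diameter 4 px, per-slice round closing radius 40 px, and one per-slice
#' round erosion of radius 1 on the tissue selection.
#'
#' @param body_threshold length-2 intensity range segmenting body/tissue.
#' @param air_threshold length-2 intensity range segmenting air.
#' @param shrinkwrap_diameter bridging diameter (pixels) of the body wrap.
#' @param closing_radius per-slice round closing radius (pixels) that fills
#'   vessels and lesions into the aerated ROI.
#' @param erosion_radius per-slice round erosion radius applied to the
#'   tissue selection (peels peripheral tissue; note that thin intra-lung
#'   tissue is also thinned by this step).
#' @param enable_optional_despeckle enable the second sweep despeckle that
#'   drops less dense body tissue picked up inside the ROI.
#' @param enable_manual_roi_export enable the export hook that saves the
#'   closed ROI for manual modification before tissue analysis.
#' @param manual_pre_roi optional `BinaryMask` applied as a rough manual
#'   pre-selection before the first threshold (the fallback for scans with
#'   strong hyperattenuation).
#' @return A `PatsParams` list.
#' @export
pats_params <- function(body_threshold = c(55, 255),
                        air_threshold = c(0, 55),
                        shrinkwrap_diameter = 4,
                        closing_radius = 40,
                        erosion_radius = 1,
                        enable_optional_despeckle = FALSE,
                        enable_manual_roi_export = FALSE,
                        manual_pre_roi = NULL) {
  stopifnot(length(body_threshold) == 2, length(air_threshold) == 2,
            body_threshold[1] <= body_threshold[2],
            air_threshold[1] <= air_threshold[2],
            shrinkwrap_diameter >= 0, closing_radius >= 0,
            erosion_radius >= 0)
  structure(list(body_threshold = body_threshold,
                 air_threshold = air_threshold,
                 shrinkwrap_diameter = shrinkwrap_diameter,
                 closing_radius = closing_radius,
                 erosion_radius = erosion_radius,
                 enable_optional_despeckle = enable_optional_despeckle,
                 enable_manual_roi_export = enable_manual_roi_export,
                 manual_pre_roi = manual_pre_roi),
            class = "PatsParams")
}

#' Build the canonical air-and-tissue task list
#'
#' Twenty operational steps: body threshold, shrink-wrap, reload, air
#' threshold, ROI = air-within-body, sweep despeckle (plus the optional
#' second sweep), save/analyze/model the aerated ROI, per-slice closing,
#' the optional manual-modification export hook, reload, tissue threshold,
#' per-slice erosion, ROI = tissue, and save/analyze/model the tissue ROI.
#'
#' @param params a [pats_params()] object.
#' @return A `TaskList` of 20 steps.
#' @export
pats_task_list <- function(params = pats_params()) {
  p <- params
  task_list(list(
    step("threshold", lo = p$body_threshold[1], hi = p$body_threshold[2]),
    step("shrinkwrap", diameter = p$shrinkwrap_diameter),
    step("reload"),
    step("threshold", lo = p$air_threshold[1], hi = p$air_threshold[2]),
    step("bitwise", op = "AND", a = "selection", b = "roi", assign = "roi"),
    step("despeckle", mode = "sweep_keep_largest", space = "3D",
         target = "roi"),
    step("despeckle", mode = "sweep_keep_largest", space = "3D",
         target = "roi", optional = TRUE,
         enabled = isTRUE(p$enable_optional_despeckle)),
    step("save_bitmaps", label = "aerated_lung"),
    step("analysis3d", label = "aerated_lung", values = "basic"),
    step("model3d", label = "aerated_lung"),
    step("morphology", op = "closing", shape = "round",
         radius = p$closing_radius, space = "2D", target = "roi"),
    step("bitwise", op = "AND", a = "selection", b = "roi", assign = "roi",
         optional = TRUE, enabled = isTRUE(p$enable_manual_roi_export)),
    step("save_bitmaps", label = "roi_for_modification", optional = TRUE,
         enabled = isTRUE(p$enable_manual_roi_export)),
    step("reload"),
    step("threshold", lo = p$body_threshold[1], hi = p$body_threshold[2]),
    step("morphology", op = "erosion", shape = "round",
         radius = p$erosion_radius, space = "2D", target = "selection"),
    step("bitwise", op = "AND", a = "roi", b = "selection", assign = "roi"),
    step("save_bitmaps", label = "lung_tissue"),
    step("analysis3d", label = "lung_tissue", values = "basic,additional"),
    step("model3d", label = "lung_tissue")),
    provenance = "built-in air+tissue defaults")
}

#' Build the ex vivo (dried lung) task list
#'
#' Threshold the dried tissue, keep the largest connected object, then
#' save/analyze/model. Analysis includes the additional values (structure
#' thickness, structure linear density).
#'
#' @param tissue_threshold length-2 intensity range for dried tissue.
#' @return A `TaskList`.
#' @export
ex_vivo_task_list <- function(tissue_threshold = c(55, 255)) {
  task_list(list(
    step("threshold", lo = tissue_threshold[1], hi = tissue_threshold[2]),
    step("bitwise", op = "AND", a = "selection", b = "roi", assign = "roi"),
    step("despeckle", mode = "sweep_keep_largest", space = "3D",
         target = "roi"),
    step("save_bitmaps", label = "lung_tissue"),
    step("analysis3d", label = "lung_tissue", values = "basic,additional"),
    step("model3d", label = "lung_tissue")),
    provenance = "built-in ex vivo defaults")
}

#' Save a task list to a structured text file
#'
#' One step per line: `[optional[!]] <name> key=value ...`. `optional`
#' marks disabled optional steps; `optional!` marks optional steps that
#' are enabled. Lines starting with `#` are comments. Round-trips through
#' [load_task_list()] are exact.
#'
#' @param tasks a `TaskList`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
save_task_list <- function(tasks, path) {
  stopifnot(inherits(tasks, "TaskList"))
  lines <- c("# patsr task list v1",
             paste0("# provenance: ", tasks$provenance))
  for (s in tasks$steps) {
    parts <- s$name
    if (length(s$params))
      parts <- c(parts, sprintf("%s=%s", names(s$params),
                                vapply(s$params, format_param, "")))
    prefix <- if (s$optional) {
      if (s$enabled) "optional! " else "optional "
    } else ""
    lines <- c(lines, paste0(prefix, paste(parts, collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

format_param <- function(v) {
  if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE) else
    as.character(v)
}

#' Load a task list from a structured text file
#'
#' @param path file written by [save_task_list()] (or by hand in the same
#'   format).
#' @return A `TaskList`.
#' @export
load_task_list <- function(path) {
  if (!file.exists(path)) stop("task list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  prov <- sub("^# provenance: ", "",
              grep("^# provenance: ", lines, value = TRUE)[1])
  if (is.na(prov)) prov <- path
  steps <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    toks <- strsplit(ln, "\\s+")[[1]]
    optional <- FALSE
    enabled <- TRUE
    if (toks[1] %in% c("optional", "optional!")) {
      optional <- TRUE
      enabled <- toks[1] == "optional!"
      toks <- toks[-1]
    }
    if (length(toks) == 0)
      stop(sprintf("task list schema violation at line %d: empty step", i))
    name <- toks[1]
    if (!name %in% TASK_OPS)
      stop(sprintf("task list schema violation at line %d: unknown operation '%s'",
                   i, name))
    params <- list()
    for (tk in toks[-1]) {
      if (!grepl("=", tk, fixed = TRUE))
        stop(sprintf("task list schema violation at line %d: expected key=value, got '%s'",
                     i, tk))
      key <- sub("=.*$", "", tk)
      val <- sub("^[^=]*=", "", tk)
      num <- suppressWarnings(as.numeric(val))
      params[[key]] <- if (!is.na(num) && grepl("^[-0-9.eE+]+$", val)) num
                       else val
    }
    steps[[length(steps) + 1]] <- list(name = name, params = params,
                                       optional = optional,
                                       enabled = enabled)
  }
  task_list(steps, provenance = prov)
}
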