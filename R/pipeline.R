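# The task-list execution engine: a small state machine holding the
# immutable grayscale image, the current ROI, and the current binary
# selection, mutated step by step exactly as analysis software walks a
# protocol.

new_pipeline_state <- function(volume, roi = NULL) {
  d <- dim(volume$data)
  full <- binary_mask(array(TRUE, d), volume$voxel_size_um)
  if (is.null(roi)) roi <- full
  check_same_shape(volume, roi)
  structure(list(image = volume, roi = roi, selection = NULL,
                 annotations = character(0), log = list(),
                 artifacts = list(), failed = FALSE),
            class = "PipelineState")
}

#' @export
print.PipelineState <- function(x, ...) {
  cat(sprintf("<PipelineState> ROI %d voxels | selection %s | %d log entries%s\n",
              sum(x$roi$data),
              if (is.null(x$selection)) "<none>" else
                sprintf("%d voxels", sum(x$selection$data)),
              length(x$log), if (x$failed) " | FAILED" else ""))
  invisible(x)
}

#' Execute a task list against a volume
#'
#' Steps mutate a `PipelineState` (image / ROI / selection) in order.
#' `save_bitmaps` steps snapshot the current ROI (and write a stack when
#' `out_dir` is given); `analysis3d` steps compute morphometry of the
#' current ROI; `model3d` steps build a surface mesh. Disabled optional
#' steps are skipped and logged. A step whose precondition fails aborts
#' with the step index; the partial state is attached to the error
#' condition and carries `failed = TRUE`.
#'
#' @param volume a `VolumeImage`.
#' @param tasks a `TaskList`.
#' @param out_dir optional directory; when given, saved ROI stacks, CSV
#'   morphometry and STL meshes are written beneath it.
#' @param roi optional initial ROI (manual pre-selection); default is the
#'   full volume.
#' @return The final `PipelineState`; per-step voxel counts are in `$log`
#'   and saved objects in `$artifacts`.
#' @export
run_task_list <- function(volume, tasks, out_dir = NULL, roi = NULL) {
  stopifnot(inherits(volume, "VolumeImage"), inherits(tasks, "TaskList"))
  state <- new_pipeline_state(volume, roi)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (i in seq_along(tasks$steps)) {
    s <- tasks$steps[[i]]
    if (s$optional && !s$enabled) {
      state$log[[length(state$log) + 1]] <-
        list(step = i, name = s$name, skipped = TRUE)
      next
    }
    state <- tryCatch(
      exec_step(state, s, out_dir),
      error = function(e) {
        state$failed <- TRUE
        cond <- structure(
          class = c("pats_step_error", "error", "condition"),
          list(message = sprintf("step %d (%s): %s", i, s$name,
                                 conditionMessage(e)),
               call = sys.call(-1), state = state, step = i))
        stop(cond)
      })
    state$log[[length(state$log) + 1]] <-
      list(step = i, name = s$name,
           roi_voxels = sum(state$roi$data),
           selection_voxels = if (is.null(state$selection)) NA_integer_
                              else sum(state$selection$data))
  }
  state
}

# internal: one step of the machine
exec_step <- function(state, s, out_dir) {
  p <- s$params
  switch(s$name,
    threshold = {
      state$selection <- threshold_global(state$image, p$lo, p$hi,
                                          roi = state$roi)
      state
    },
    shrinkwrap = {
      src <- if (is.null(state$selection)) state$roi else state$selection
      state$roi <- shrinkwrap_roi(src, stretch_over_holes = TRUE,
                                  diameter = p$diameter)
      state
    },
    reload = {
      state$selection <- NULL
      state
    },
    bitwise = {
      pick <- function(which) {
        switch(which,
               selection = {
                 if (is.null(state$selection))
                   stop("bitwise step references an empty selection")
                 state$selection
               },
               roi = state$roi,
               stop("bitwise operand must be 'selection' or 'roi'"))
      }
      res <- bitwise_combine(pick(p$a), pick(p$b), op = p$op)
      if (identical(p$assign, "roi")) state$roi <- res
      else state$selection <- res
      state
    },
    despeckle = {
      if (identical(p$target, "roi")) {
        state$roi <- despeckle(state$roi, mode = p$mode, space = p$space,
                               size_threshold = p$size_threshold)
      } else {
        if (is.null(state$selection)) stop("no selection to despeckle")
        state$selection <- despeckle(state$selection, mode = p$mode,
                                     space = p$space,
                                     size_threshold = p$size_threshold)
      }
      state
    },
    morphology = {
      el <- structuring_element(p$shape, p$radius, p$space)
      if (identical(p$target, "roi")) {
        state$roi <- morphological_operation(state$roi, p$op, el)
      } else {
        if (is.null(state$selection)) stop("no selection for morphology")
        state$selection <- morphological_operation(state$selection, p$op, el)
      }
      state
    },
    save_bitmaps = {
      state$artifacts[[paste0("roi_", p$label)]] <- state$roi
      if (!is.null(out_dir)) {
        dir <- file.path(out_dir, paste0("roi_", p$label))
        write_roi_stack(state$roi, dir, prefix = paste0(p$label, "_"))
      }
      state
    },
    analysis3d = {
      vals <- strsplit(p$values %||% "basic", ",")[[1]]
      voi <- if (identical(p$voi, "grid")) NULL else state$roi
      m <- morphometry(state$roi, roi = voi, values = vals)
      state$artifacts[[paste0("morphometry_", p$label)]] <- m
      if (!is.null(out_dir))
        write_morphometry_csv(stats::setNames(list(m), p$label),
                              file.path(out_dir,
                                        paste0("morphometry_", p$label,
                                               ".csv")))
      state
    },
    model3d = {
      mesh <- surface_mesh(state$roi)
      state$artifacts[[paste0("mesh_", p$label)]] <- mesh
      if (!is.null(out_dir))
        write_mesh_stl(mesh, file.path(out_dir,
                                       paste0("mesh_", p$label, ".stl")))
      state
    },
    comment = {
      state$annotations <- c(state$annotations, p$text %||% "")
      state
    },
    stop("unresolvable step: ", s$name))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Automated pulmonary air and tissue segmentation
#'
#' Runs the full air+tissue protocol (see [pats_task_list()]): the body is
#' thresholded and shrink-wrapped into a body ROI; air within the body is
#' thresholded and swept down to its largest connected component (the
#' aerated lung, airways included); a per-slice round closing fills
#' vessels and dense tissue back into the lung envelope; the tissue range
#' is re-thresholded inside that envelope, eroded by one pixel per slice
#' to peel peripheral tissue, and analyzed.
#'
#' Voxels at the shared cut point of the air and tissue ranges can fall in
#' both ROIs; any such overlap is removed from the tissue ROI and its
#' voxel count logged.
#'
#' @param volume a `VolumeImage`.
#' @param params a [pats_params()] object.
#' @param out_dir optional output directory for ROI stacks, CSV reports and
#'   meshes.
#' @return A `PatsResult` with `aerated_roi`, `tissue_roi`,
#'   `aerated_morphometry`, `tissue_morphometry`, `aerated_mesh`,
#'   `tissue_mesh` and the step `log`.
#' @export
pats_segment <- function(volume, params = pats_params(), out_dir = NULL) {
  stopifnot(inherits(volume, "VolumeImage"))
  tasks <- pats_task_list(params)
  state <- tryCatch(
    run_task_list(volume, tasks, out_dir = out_dir,
                  roi = params$manual_pre_roi),
    pats_step_error = function(e) {
      if (grepl("no objects: empty mask", conditionMessage(e)))
        stop("segmentation failed: no lung air", call. = FALSE)
      stop(e)
    })
  aerated <- state$artifacts$roi_aerated_lung
  tissue <- state$artifacts$roi_lung_tissue
  overlap <- sum(aerated$data & tissue$data)
  tissue_m <- state$artifacts$morphometry_lung_tissue
  tissue_mesh <- state$artifacts$mesh_lung_tissue
  if (overlap > 0) {
    message(sprintf("%d voxels at the shared threshold cut point removed from the tissue ROI", overlap))
    tissue <- bitwise_combine(tissue, aerated, "SUB")
    tissue_m <- morphometry(tissue, roi = tissue,
                            values = c("basic", "additional"))
    tissue_mesh <- surface_mesh(tissue)
  }
  aerated_mm3 <- state$artifacts$morphometry_aerated_lung$total_volume_mm3
  if (aerated_mm3 < 1)
    warning("implausible lung volume: aerated ROI below 1 mm^3")
  structure(list(
    aerated_roi = aerated,
    tissue_roi = tissue,
    aerated_morphometry = state$artifacts$morphometry_aerated_lung,
    tissue_morphometry = tissue_m,
    aerated_mesh = state$artifacts$mesh_aerated_lung,
    tissue_mesh = tissue_mesh,
    overlap_voxels = overlap,
    log = state$log), class = "PatsResult")
}

#' @export
print.PatsResult <- function(x, ...) {
  cat(sprintf("<PatsResult> aerated %.4g mm^3 | tissue %.4g mm^3\n",
              x$aerated_morphometry$total_volume_mm3,
              x$tissue_morphometry$total_volume_mm3))
  invisible(x)
}

#' Ex vivo (dried lung) segmentation and quantitation
#'
#' For high-resolution scans of chemically dried, fixed lungs: dried
#' tissue is bright on an air background, so the tissue mask is a global
#' threshold swept down to its largest connected object. Morphometry (on
#' the full scan VOI) reports tissue volume, structure thickness and
#' structure linear density.
#'
#' @param volume a `VolumeImage` of a dried/fixed lung on air background.
#' @param tissue_threshold length-2 intensity range for the dried tissue.
#' @param out_dir optional output directory.
#' @return List with `tissue_roi` (`BinaryMask`), `morphometry`
#'   (`MorphometryResult`) and `mesh` (`TriangleMesh`).
#' @export
ex_vivo_segment <- function(volume, tissue_threshold = c(55, 255),
                            out_dir = NULL) {
  stopifnot(inherits(volume, "VolumeImage"))
  tasks <- ex_vivo_task_list(tissue_threshold)
  tasks$steps[[5]]$params$voi <- "grid"
  state <- tryCatch(
    run_task_list(volume, tasks, out_dir = out_dir),
    pats_step_error = function(e) {
      if (grepl("no objects: empty mask", conditionMessage(e)))
        stop("segmentation failed: no tissue in threshold range",
             call. = FALSE)
      stop(e)
    })
  list(tissue_roi = state$artifacts$roi_lung_tissue,
       morphometry = state$artifacts$morphometry_lung_tissue,
       mesh = state$artifacts$mesh_lung_tissue,
       log = state$log)
}
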