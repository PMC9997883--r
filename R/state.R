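#' Lattice state of a CPM simulation
#'
#' The grid is a 2D torus stored as two matrices indexed `[x, y]` with
#' `nrow = width` and `ncol = height`: `identity` maps each pixel to a cell
#' id (0 = background medium) and `activity` holds the per-pixel protrusive
#' activity (in MCS; 0 on background). `cells` is a data frame with one row
#' per cell id carrying that cell's type and constraint parameters, so
#' per-cell settings (e.g. the transient keratinocyte perimeter target
#' during tissue seeding) can differ from the type defaults.
#'
#' @param width,height Grid dimensions in pixels.
#' @param identity Integer matrix `width x height` of cell ids, or `NULL`
#'   for an all-background grid.
#' @param activity Numeric matrix of activities, or `NULL` for all zero.
#' @param cells Data frame with columns `id`, `type` (1 = T cell,
#'   2 = keratinocyte), `V_target`, `lambda_V`, `P_target`, `lambda_P`,
#'   `max_act`, `lambda_act`. Ids must be `1:nrow(cells)`.
#' @return An object of class `cpm_state`.
#' @export
lattice_state <- function(width, height, identity = NULL, activity = NULL,
                          cells = empty_cells()) {
  if (is.null(identity)) {
    identity <- matrix(0L, nrow = width, ncol = height)
  }
  storage.mode(identity) <- "integer"
  if (is.null(activity)) {
    activity <- matrix(0, nrow = width, ncol = height)
  }
  state <- structure(list(width = as.integer(width),
                          height = as.integer(height),
                          identity = identity, activity = activity,
                          cells = cells),
                     class = "cpm_state")
  validate_state(state)
  state
}

#' @rdname lattice_state
#' @export
empty_cells <- function() {
  data.frame(id = integer(), type = integer(), V_target = numeric(),
             lambda_V = numeric(), P_target = numeric(),
             lambda_P = numeric(), max_act = numeric(),
             lambda_act = numeric())
}

validate_state <- function(state) {
  stopifnot(is.matrix(state$identity), is.matrix(state$activity),
            nrow(state$identity) == state$width,
            ncol(state$identity) == state$height,
            dim(state$identity)[1] == dim(state$activity)[1],
            dim(state$identity)[2] == dim(state$activity)[2])
  ids <- state$cells$id
  if (length(ids) > 0 && !identical(as.integer(ids), seq_along(ids))) {
    stop("cell ids must be 1:nrow(cells)")
  }
  used <- unique(as.vector(state$identity))
  if (!all(used %in% c(0L, ids))) {
    stop("identity matrix refers to unknown cell ids")
  }
  if (any(state$activity < 0)) stop("negative activity")
  if (any(state$activity[state$identity == 0L] != 0)) {
    stop("background pixels must have zero activity")
  }
  invisible(state)
}

# Append one cell row; returns list(state, id)
add_cell <- function(state, type, constraints, max_act = 0,
                     lambda_act = 0) {
  id <- nrow(state$cells) + 1L
  state$cells <- rbind(state$cells, data.frame(
    id = id, type = as.integer(type),
    V_target = constraints$V_target, lambda_V = constraints$lambda_V,
    P_target = constraints$P_target, lambda_P = constraints$lambda_P,
    max_act = max_act, lambda_act = lambda_act))
  list(state = state, id = id)
}

# Per-cell parameter matrix in the layout the C++ kernel expects
cell_param_matrix <- function(state) {
  cb <- state$cells
  if (nrow(cb) == 0) {
    return(matrix(0, nrow = 0, ncol = 7))
  }
  as.matrix(cb[, c("type", "V_target", "lambda_V", "P_target", "lambda_P",
                   "max_act", "lambda_act")])
}

#' @export
print.cpm_state <- function(x, ...) {
  cat(sprintf("CPM lattice %dx%d (torus), %d cell(s)\n",
              x$width, x$height, nrow(x$cells)))
  if (nrow(x$cells) > 0) {
    vols <- tabulate(x$identity[x$identity > 0], nbins = nrow(x$cells))
    tp <- c("tcell", "keratinocyte")[x$cells$type]
    cat(sprintf("  cell %d (%s): %d px\n", x$cells$id, tp, vols), sep = "")
  }
  invisible(x)
}

#' Per-cell pixel volumes
#'
#' @param state A `cpm_state`.
#' @return Integer vector of pixel counts, one per cell id.
#' @export
cell_volumes <- function(state) {
  tabulate(state$identity[state$identity > 0L], nbins = nrow(state$cells))
}

#' Pixel coordinates of one cell
#'
#' @param state A `cpm_state`.
#' @param cell_id Cell id.
#' @return Two-column matrix of `(x, y)` pixel coordinates (1-based).
#' @export
cell_pixels <- function(state, cell_id) {
  which(state$identity == cell_id, arr.ind = TRUE, useNames = FALSE)
}
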