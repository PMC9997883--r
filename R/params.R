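#' Physical CPM parameters
#'
#' Bundles the temperature, adhesion energies and the per-cell-type volume
#' and perimeter constraints of the model. Volumes are in pixels, perimeters
#' count Moore-neighbour boundary pairs, and all energies are in the
#' dimensionless CPM units conventional for this model family.
#'
#' @param temperature Metropolis temperature (energy units).
#' @param tcell Named list with `V_target`, `lambda_V`, `P_target`,
#'   `lambda_P` for the migrating T cell.
#' @param keratinocyte As `tcell`, for the obstacle keratinocytes, or `NULL`
#'   in environments without tissue.
#' @param adhesion Symmetric 3x3 matrix of contact energies per unlike
#'   neighbouring pixel pair, with dimnames `bg`, `tcell`, `keratinocyte`;
#'   `adhesion["bg","bg"]` must be 0.
#' @return An object of class `cpm_params`.
#' @seealso [free_params()], [skin_params()] for the two standard
#'   environments.
#' @export
cpm_params <- function(temperature = 20,
                       tcell = list(V_target = 500, lambda_V = 30,
                                    P_target = 260, lambda_P = 2),
                       keratinocyte = NULL,
                       adhesion = NULL) {
  if (is.null(adhesion)) {
    adhesion <- matrix(0, 3, 3,
                       dimnames = list(c("bg", "tcell", "keratinocyte"),
                                       c("bg", "tcell", "keratinocyte")))
    adhesion["bg", "tcell"] <- adhesion["tcell", "bg"] <- 20
    adhesion["tcell", "tcell"] <- 20
  }
  stopifnot(is.matrix(adhesion), nrow(adhesion) == 3, ncol(adhesion) == 3,
            isTRUE(all.equal(adhesion, t(adhesion))),
            adhesion[1, 1] == 0)
  req <- c("V_target", "lambda_V", "P_target", "lambda_P")
  stopifnot(all(req %in% names(tcell)))
  if (!is.null(keratinocyte)) stopifnot(all(req %in% names(keratinocyte)))
  structure(list(temperature = temperature, tcell = tcell,
                 keratinocyte = keratinocyte, adhesion = adhesion),
            class = "cpm_params")
}

#' Standard parameters for the empty ("free") environment
#'
#' A single T cell on an empty torus: target volume 500 pixels
#' (lambda 30), target perimeter 260 (lambda 2), cell-background adhesion
#' 20, temperature 20.
#'
#' @return A `cpm_params` object.
#' @export
free_params <- function() cpm_params()

#' Standard parameters for the packed "skin" environment
#'
#' T-cell constraints as in [free_params()]; keratinocytes have target
#' volume 750 (lambda 30) and target perimeter 330 (lambda 10; 200 is used
#' transiently while the tissue is seeded, see [init_skin()]).
#' Keratinocyte-keratinocyte adhesion is 200, T cell-keratinocyte adhesion
#' 2, and both cell types have adhesion 20 with the background.
#'
#' @return A `cpm_params` object.
#' @export
skin_params <- function() {
  J <- matrix(0, 3, 3,
              dimnames = list(c("bg", "tcell", "keratinocyte"),
                              c("bg", "tcell", "keratinocyte")))
  J["bg", "tcell"] <- J["tcell", "bg"] <- 20
  J["bg", "keratinocyte"] <- J["keratinocyte", "bg"] <- 20
  J["tcell", "tcell"] <- 20
  J["tcell", "keratinocyte"] <- J["keratinocyte", "tcell"] <- 2
  J["keratinocyte", "keratinocyte"] <- 200
  cpm_params(keratinocyte = list(V_target = 750, lambda_V = 30,
                                 P_target = 330, lambda_P = 10),
             adhesion = J)
}

#' Evolvable genotype of an Act cell
#'
#' The two heritable motility parameters: `max_act`, the number of MCS a
#' newly gained pixel retains protrusive activity, and `lambda_act`, the
#' energetic weight of the protrusion feedback. Both must be strictly
#' positive; mutation acts on the log scale and preserves this. `max_act`
#' is treated as a continuous quantity throughout (activity still decays by
#' 1 per MCS).
#'
#' @param max_act Activity memory (MCS), > 0.
#' @param lambda_act Protrusion strength (energy units), > 0.
#' @return A named numeric vector of class `genotype`.
#' @export
genotype <- function(max_act, lambda_act) {
  stopifnot(is.numeric(max_act), is.numeric(lambda_act),
            length(max_act) == 1, length(lambda_act) == 1,
            max_act > 0, lambda_act > 0)
  structure(c(max_act = as.numeric(max_act),
              lambda_act = as.numeric(lambda_act)),
            class = "genotype")
}
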