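#' Kinetic parameters of the dual-input 4C liver model
#'
#' The four-compartment model tracks free FDG in tissue (C_E), cytosolic
#' FDG6P (C_M) and FDG6P sequestered in the endoplasmic reticulum (C_R).
#' Rate constants are in min^-1 except K1 (mL min^-1 mL^-1); volume terms
#' are dimensionless fractions.
#'
#' @param K1 Blood-to-tissue transport rate (GLUT).
#' @param k2 Tissue-to-blood clearance rate.
#' @param k3 Phosphorylation rate (hexokinase).
#' @param k5 FDG6P entry rate into the ER (G6PT).
#' @param k6 Dephosphorylation rate in the ER (G6Pase).
#' @param HPI Hepatic artery perfusion index, in `[0, 1]`.
#' @param Vb Fractional blood volume, in `[0, 1]`.
#' @param Vi Fractional interstitial volume, in `[0, 1 - Vb]`.
#' @param v ER-to-cytosol volume ratio, >= 0.
#' @return An object of class `c("kinetic_params_4c", "kinetic_params")`.
#' @export
kinetic_params_4c <- function(K1, k2, k3, k5, k6, HPI, Vb, Vi, v) {
  p <- list(K1 = K1, k2 = k2, k3 = k3, k5 = k5, k6 = k6,
            HPI = HPI, Vb = Vb, Vi = Vi, v = v)
  if (any(!vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x), logical(1))))
    stop("all kinetic parameters must be finite scalars")
  rates <- c(K1, k2, k3, k5, k6)
  if (any(rates < 0)) stop("rate constants must be nonnegative")
  if (HPI < 0 || HPI > 1) stop("HPI must lie in [0, 1]")
  if (Vb < 0 || Vb > 1 || Vi < 0 || Vi > 1)
    stop("volume fractions must lie in [0, 1]")
  if (Vb + Vi > 1 + 1e-12) stop("Vb + Vi must not exceed 1")
  if (v < 0) stop("`v` must be nonnegative")
  structure(p, class = c("kinetic_params_4c", "kinetic_params"))
}

#' Kinetic parameters of the dual-input 3C liver model
#'
#' The three-compartment (two-tissue) model tracks free FDG (C_E) and FDG6P
#' (C_M); `k4` is the dephosphorylation rate returning FDG6P to free FDG.
#'
#' @inheritParams kinetic_params_4c
#' @param k4 Dephosphorylation rate (min^-1).
#' @return An object of class `c("kinetic_params_3c", "kinetic_params")`.
#' @export
kinetic_params_3c <- function(K1, k2, k3, k4, HPI, Vb) {
  p <- list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, HPI = HPI, Vb = Vb)
  if (any(!vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x), logical(1))))
    stop("all kinetic parameters must be finite scalars")
  if (any(c(K1, k2, k3, k4) < 0)) stop("rate constants must be nonnegative")
  if (HPI < 0 || HPI > 1) stop("HPI must lie in [0, 1]")
  if (Vb < 0 || Vb > 1) stop("Vb must lie in [0, 1]")
  structure(p, class = c("kinetic_params_3c", "kinetic_params"))
}

#' @export
print.kinetic_params <- function(x, ...) {
  cls <- if (inherits(x, "kinetic_params_4c")) "4C" else "3C"
  cat(sprintf("<kinetic_params %s> %s\n", cls,
              paste(sprintf("%s=%.4g", names(x), unlist(x)),
                    collapse = ", ")))
  invisible(x)
}

#' Compartmental system matrix
#'
#' The state matrix M of the linear system `dC/dt = M C + K1 C_B e1`.
#' For the 4C model (states C_E, C_M, C_R):
#' `M = [[-(k2+k3), 0, k6], [k3, -k5, 0], [0, k5, -k6]]`;
#' for the 3C model (states C_E, C_M):
#' `M = [[-(k2+k3), k4], [k3, -k4]]`.
#' In both, column sums are `(-k2, 0, ...)`: tracer leaves the tissue system
#' only through k2.
#'
#' @param p A [kinetic_params_4c()] or [kinetic_params_3c()] object.
#' @return The rate matrix (min^-1).
#' @export
system_matrix <- function(p) UseMethod("system_matrix")

#' @export
system_matrix.kinetic_params_4c <- function(p) {
  matrix(c(-(p$k2 + p$k3), 0, p$k6,
           p$k3, -p$k5, 0,
           0, p$k5, -p$k6),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("C_E", "C_M", "C_R"), c("C_E", "C_M", "C_R")))
}

#' @export
system_matrix.kinetic_params_3c <- function(p) {
  matrix(c(-(p$k2 + p$k3), p$k4,
           p$k3, -p$k4),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("C_E", "C_M"), c("C_E", "C_M")))
}

#' Output mixing weights
#'
#' Weights combining the compartment concentrations into the measured tissue
#' concentration `C_T = alpha . C + Vb C_B`.  For the 4C model, with
#' `v_r = v / (1 + v)` (the ER fraction of non-vascular, non-interstitial
#' space):
#' `alpha1 = Vi + (1 - v_r)(1 - Vb - Vi)`,
#' `alpha2 = (1 - v_r)(1 - Vb - Vi)`,
#' `alpha3 = v_r (1 - Vb - Vi)`.
#' For the 3C model `alpha1 = alpha2 = 1 - Vb`.
#'
#' @param p A `kinetic_params` object.
#' @return A list with `alpha` (numeric weight vector) and `v_r` (0 for 3C).
#' @export
alpha_weights <- function(p) UseMethod("alpha_weights")

#' @export
alpha_weights.kinetic_params_4c <- function(p) {
  if (p$Vb + p$Vi > 1 + 1e-12) stop("Vb + Vi must not exceed 1")
  v_r <- p$v / (1 + p$v)
  rest <- 1 - p$Vb - p$Vi
  list(alpha = c(alpha1 = p$Vi + (1 - v_r) * rest,
                 alpha2 = (1 - v_r) * rest,
                 alpha3 = v_r * rest),
       v_r = v_r)
}

#' @export
alpha_weights.kinetic_params_3c <- function(p) {
  list(alpha = c(alpha1 = 1 - p$Vb, alpha2 = 1 - p$Vb), v_r = 0)
}
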