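#' @useDynLib restdnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

BOHR_PER_ANGSTROM <- 1 / 0.529177210903

#' Hartree to kcal/mol conversion factor
#'
#' Energies are carried in Hartree internally; kcal/mol appears only at
#' reporting boundaries.
#' @export
hartree_to_kcalmol <- 627.509474

.element_numbers <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7,
                      O = 8, F = 9, Ne = 10)

# Shared STO-3G contraction coefficient sets (valence-shell coefficients are
# identical across first-row elements; exponents differ).
.sto3g_s_coef  <- c(0.15432897, 0.53532814, 0.44463454)
.sto3g_s2_coef <- c(-0.09996723, 0.39951283, 0.70011547)
.sto3g_p_coef  <- c(0.15591627, 0.60768372, 0.39195739)

# basis definitions: per element, a list of shells (l, exps, coefs)
.basis_library <- list(
  "sto-3g" = list(
    H = list(
      list(l = 0L, exps = c(3.42525091, 0.62391373, 0.16885540),
           coefs = .sto3g_s_coef)
    ),
    C = list(
      list(l = 0L, exps = c(71.6168370, 13.0450960, 3.5305122),
           coefs = .sto3g_s_coef),
      list(l = 0L, exps = c(2.9412494, 0.6834831, 0.2222899),
           coefs = .sto3g_s2_coef),
      list(l = 1L, exps = c(2.9412494, 0.6834831, 0.2222899),
           coefs = .sto3g_p_coef)
    ),
    N = list(
      list(l = 0L, exps = c(99.1061690, 18.0523120, 4.8856602),
           coefs = .sto3g_s_coef),
      list(l = 0L, exps = c(3.7804559, 0.8784966, 0.2857144),
           coefs = .sto3g_s2_coef),
      list(l = 1L, exps = c(3.7804559, 0.8784966, 0.2857144),
           coefs = .sto3g_p_coef)
    ),
    O = list(
      list(l = 0L, exps = c(130.7093200, 23.8088610, 6.4436083),
           coefs = .sto3g_s_coef),
      list(l = 0L, exps = c(5.0331513, 1.1695961, 0.3803890),
           coefs = .sto3g_s2_coef),
      list(l = 1L, exps = c(5.0331513, 1.1695961, 0.3803890),
           coefs = .sto3g_p_coef)
    )
  ),
  "6-31g" = list(
    H = list(
      list(l = 0L, exps = c(18.7311370, 2.8253937, 0.6401217),
           coefs = c(0.03349460, 0.23472695, 0.81375733)),
      list(l = 0L, exps = 0.1612778, coefs = 1.0)
    ),
    O = list(
      list(l = 0L,
           exps = c(5484.6717, 825.23495, 188.04696, 52.964500, 16.897570,
                    5.7996353),
           coefs = c(0.0018311, 0.0139501, 0.0684451, 0.2327143, 0.4701930,
                     0.3585209)),
      list(l = 0L, exps = c(15.539616, 3.5999336, 1.0137618),
           coefs = c(-0.1107775, -0.1480263, 1.1307670)),
      list(l = 1L, exps = c(15.539616, 3.5999336, 1.0137618),
           coefs = c(0.0708743, 0.3397528, 0.7271586)),
      list(l = 0L, exps = 0.2700058, coefs = 1.0),
      list(l = 1L, exps = 0.2700058, coefs = 1.0)
    )
  )
)

#' Available basis sets
#' @return character vector of basis-set names understood by
#'   [run_mean_field()].
#' @export
available_bases <- function() names(.basis_library)

# Expand per-element shells into a list of contracted Cartesian AOs at the
# molecular geometry; coefficients are rescaled so each contracted AO is
# normalized to unit self-overlap.
build_basis_functions <- function(geometry, basis_name) {
  basis_name <- tolower(basis_name)
  lib <- .basis_library[[basis_name]]
  if (is.null(lib)) {
    stop("unknown basis set '", basis_name, "'; available: ",
         paste(available_bases(), collapse = ", "), call. = FALSE)
  }
  fns <- list()
  atom_of <- integer(0)
  for (ia in seq_along(geometry$atoms)) {
    el <- geometry$atoms[ia]
    shells <- lib[[el]]
    if (is.null(shells)) {
      stop("basis '", basis_name, "' has no parameters for element '", el, "'",
           call. = FALSE)
    }
    origin <- geometry$coords[ia, ] * BOHR_PER_ANGSTROM
    for (sh in shells) {
      comps <- if (sh$l == 0L) list(c(0L, 0L, 0L)) else
        list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
      for (lmn in comps) {
        fns[[length(fns) + 1L]] <- list(l = as.integer(lmn),
                                        origin = as.numeric(origin),
                                        exps = sh$exps, coefs = sh$coefs)
        atom_of <- c(atom_of, ia)
      }
    }
  }
  # contracted normalization: scale coefs so <chi|chi> = 1
  one <- one_electron_integrals(fns, numeric(0), matrix(0.0, 0, 3))
  snorm <- sqrt(diag(one$S))
  for (k in seq_along(fns)) fns[[k]]$coefs <- fns[[k]]$coefs / snorm[k]
  list(functions = fns, atom_of = atom_of)
}
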