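#' Build a SolverConfig
#'
#' Defaults encode the published hyperparameter setting: lambda1 = 70 for
#' the field regularizer; the `"lesjakdb"` preset uses (lambda2, lambda3)
#' = (16, 5) (all kinds of lesion evolution, FLAIR), the `"msseg2"` preset
#' (25, 3) (new appearing lesions only).  Stopping rules default to
#' relative-change tolerance 2e-3 with cap 300 for ADMM and 1e-3 with cap
#' 5 for the outer alternation.  The ADMM penalty mu and the pyramid
#' schedule are implementation choices (see the methods vignette).
#'
#' @param preset `"lesjakdb"` or `"msseg2"`, selecting the (lambda2,
#'   lambda3) pair.
#' @param lambda1,lambda2,lambda3 energy weights; explicit values override
#'   the preset.
#' @param mu ADMM penalty (> 0).
#' @param pyramidLevels,pyramidFactor,warpsPerLevel coarse-to-fine schedule.
#' @param admmTol,admmMaxIter ADMM stopping rule.
#' @param outerTol,outerMaxIter outer alternation stopping rule.
#' @return A [SolverConfig-class] object.
#' @examples
#' solverConfig()                      # LesjakDB preset
#' solverConfig("msseg2", lambda1 = 70)
#' @export
solverConfig <- function(preset = c("lesjakdb", "msseg2"),
                         lambda1 = 70, lambda2 = NULL, lambda3 = NULL,
                         mu = 1.0,
                         pyramidLevels = 3L, pyramidFactor = 2,
                         warpsPerLevel = 2L,
                         admmTol = 2e-3, admmMaxIter = 300L,
                         outerTol = 1e-3, outerMaxIter = 5L) {
    preset <- match.arg(preset)
    pre <- switch(preset,
                  lesjakdb = c(16, 5),
                  msseg2 = c(25, 3))
    if (is.null(lambda2)) lambda2 <- pre[1L]
    if (is.null(lambda3)) lambda3 <- pre[2L]
    new("SolverConfig",
        lambda1 = as.numeric(lambda1), lambda2 = as.numeric(lambda2),
        lambda3 = as.numeric(lambda3), mu = as.numeric(mu),
        pyramidLevels = as.integer(pyramidLevels),
        pyramidFactor = as.numeric(pyramidFactor),
        warpsPerLevel = as.integer(warpsPerLevel),
        admmTol = as.numeric(admmTol), admmMaxIter = as.integer(admmMaxIter),
        outerTol = as.numeric(outerTol),
        outerMaxIter = as.integer(outerMaxIter))
}

## Config <-> plain list (for YAML round trips and CLI overrides).
.config_to_list <- function(cfg) {
    nm <- slotNames("SolverConfig")
    stats::setNames(lapply(nm, function(s) slot(cfg, s)), nm)
}

.config_from_list <- function(lst) {
    base <- .config_to_list(solverConfig())
    lst <- lst[names(lst) %in% names(base)]
    do.call(solverConfig, modifyList(base, lst))
}
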