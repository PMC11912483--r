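#' Engine configuration
#'
#' Collects every threshold and multipole parameter of the Coulomb builders.
#' Defaults are the production settings: conservative single-build multipole
#' orders (`Lmax_step1 = 10`, first up-translation 6 for the shell-pair
#' hierarchy; `Lmax_step2 = 6` with first up-translation 10 from exact atomic
#' auxiliary bubbles), multipole screening `T_screen = 1e-10`, `R_allow = 1`,
#' `TargetDim1 = 150` objects per bottom bubble, `TargetDim2 = 3` children
#' per superbubble, at most 20 levels, absolute order cap 44, direct-SCF
#' neglect threshold `Thresh = 1e-10`, and an incremental driver that
#' restarts with a full accurate build every 10 iterations.
#'
#' @param T_sphere extent threshold (Bohr-space magnitude bound).
#' @param T_screen multipole coefficient screening threshold.
#' @param R_allow far-field safety factor (>= 1 for a convergent expansion).
#' @param R_allow_mode `"ratio"` (allowed iff distance >= R_allow * (extent +
#'   radius), boundary inclusive) or `"offset"` (distance - extent - radius
#'   >= R_allow), the alternative additive-margin reading.
#' @param Lmax_step1 shell-pair bubble expansion order (auxiliary-vector step).
#' @param Lincr1_step1 first up-translation increment, pair hierarchy.
#' @param Lmax_step2 contracted shell-pair expansion order (J-assembly step).
#' @param Lincr1_step2 first up-translation increment, auxiliary hierarchy.
#' @param Lincr2 subsequent up-translation increments (both hierarchies).
#' @param TargetDim1 objects per bottom-level bubble.
#' @param TargetDim2 children per superbubble.
#' @param L_abs_max absolute multipole order cap.
#' @param max_levels maximum number of hierarchy levels.
#' @param Thresh direct-SCF neglect threshold for Schwarz skipping.
#' @param prescreen primitive-pair prescreen threshold.
#' @param restart_cycle full-rebuild period of the incremental driver.
#' @param accurate_rebuild use high-accuracy multipole settings on full
#'   rebuilds while incremental updates run at the reduced settings.
#' @param incr_Lmax_step1,incr_Lincr1_step1,incr_Lincr2 reduced-accuracy
#'   settings used for incremental updates when `accurate_rebuild` is on.
#' @param step2_pair_multipoles `"contracted"` (compact, non-terminating,
#'   taken to `Lmax_step2`) or `"primitive"` (exact per-primitive expansions).
#' @param aux_bubbles `"atomic"` (exact terminating bottom level) or
#'   `"kmeans"`.
#' @param diffuse_cutoff extent (Bohr) above which an object is routed to the
#'   always-near-field throwaway bubble.
#' @param eri4_cap refuse four-index builds above this many basis functions.
#' @param seed integer seed recorded with the hierarchy.
#' @return list of class `bupo_config`.
#' @export
bupo_config <- function(T_sphere = 1e-8, T_screen = 1e-10,
                        R_allow = 1.0, R_allow_mode = c("ratio", "offset"),
                        Lmax_step1 = 10L, Lincr1_step1 = 6L,
                        Lmax_step2 = 6L, Lincr1_step2 = 10L, Lincr2 = 10L,
                        TargetDim1 = 150L, TargetDim2 = 3L,
                        L_abs_max = 44L, max_levels = 20L,
                        Thresh = 1e-10, prescreen = 1e-12,
                        restart_cycle = 10L, accurate_rebuild = TRUE,
                        incr_Lmax_step1 = 6L, incr_Lincr1_step1 = 4L,
                        incr_Lincr2 = 3L,
                        step2_pair_multipoles = c("contracted", "primitive"),
                        aux_bubbles = c("atomic", "kmeans"),
                        diffuse_cutoff = 20, eri4_cap = 256L, seed = 1L) {
  cfg <- list(
    T_sphere = T_sphere, T_screen = T_screen,
    R_allow = R_allow, R_allow_mode = match.arg(R_allow_mode),
    Lmax_step1 = as.integer(Lmax_step1), Lincr1_step1 = as.integer(Lincr1_step1),
    Lmax_step2 = as.integer(Lmax_step2), Lincr1_step2 = as.integer(Lincr1_step2),
    Lincr2 = as.integer(Lincr2),
    TargetDim1 = as.integer(TargetDim1), TargetDim2 = as.integer(TargetDim2),
    L_abs_max = as.integer(L_abs_max), max_levels = as.integer(max_levels),
    Thresh = Thresh, prescreen = prescreen,
    restart_cycle = as.integer(restart_cycle),
    accurate_rebuild = isTRUE(accurate_rebuild),
    incr_Lmax_step1 = as.integer(incr_Lmax_step1),
    incr_Lincr1_step1 = as.integer(incr_Lincr1_step1),
    incr_Lincr2 = as.integer(incr_Lincr2),
    step2_pair_multipoles = match.arg(step2_pair_multipoles),
    aux_bubbles = match.arg(aux_bubbles),
    diffuse_cutoff = diffuse_cutoff, eri4_cap = as.integer(eri4_cap),
    seed = as.integer(seed)
  )
  stopifnot(cfg$T_sphere > 0, cfg$T_screen > 0, cfg$Thresh > 0,
            cfg$prescreen > 0, cfg$R_allow >= 1 || !is.finite(cfg$R_allow))
  class(cfg) <- "bupo_config"
  cfg
}

#' @export
print.bupo_config <- function(x, ...) {
  cat("bupo_config:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# flat key = value config file support (CLI)
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  args <- stats::setNames(
    lapply(kv, function(x) utils::type.convert(x[2L], as.is = TRUE)),
    vapply(kv, `[[`, "", 1L)
  )
  do.call(bupo_config, args)
}
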