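#' Read a study configuration from YAML
#'
#' Parses a YAML study configuration into the objects used by
#' [assess_allocation_bias()]. The file has top-level fields `procedure`
#' (`sidak` or `all_or_none`), `alpha`, `r`, `seed`, `rps` (a list of
#' randomization-procedure specifications such as `{name: CHEN, p: 0.67,
#' b: 2}`) and `cases`, a list of settings each giving `N`, `m`, the bias
#' effects (either `eta` directly, or `nu` together with `effect_sizes`,
#' scalars recycled over endpoints), and optionally `sigma` (default 1),
#' `rho` (an exchangeable endpoint correlation) or `corr` (an explicit
#' matrix as a list of rows).
#'
#' Configurations reproducing the package's reference simulation settings are
#' shipped under `system.file("extdata", package = "allocbias")`.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `procedure`, `alpha`, `r`, `seed`, `rps`
#'   (list of [rp_spec()]) and `cases` (list of lists with `design`,
#'   `policy` and a descriptive `label`).
#' @examples
#' cfg <- read_study_config(system.file("extdata", "table3.yaml",
#'                                      package = "allocbias"))
#' cfg$cases[[1]]$label
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("procedure", "rps", "cases"))
    if (is.null(raw[[f]])) stop("config is missing '", f, "'", call. = FALSE)
  procedure <- match.arg(raw$procedure, c("sidak", "all_or_none"))
  alpha <- if (is.null(raw$alpha)) 0.05 else raw$alpha
  rps <- lapply(raw$rps, function(s)
    rp_spec(s[["name"]], p = s[["p"]], b = s[["b"]],
            block_size = s[["block_size"]]))
  cases <- lapply(raw$cases, function(cs) {
    if (is.null(cs$N) || is.null(cs$m))
      stop("every case needs 'N' and 'm'", call. = FALSE)
    m <- cs$m
    if (!is.null(cs$eta)) {
      policy <- bias_policy(rep_len(as.numeric(cs$eta), m))
      label <- sprintf("eta=%s", paste(signif(policy$eta, 4), collapse = ","))
    } else if (!is.null(cs$nu) && !is.null(cs$effect_sizes)) {
      policy <- effect_size_eta(cs$nu, as.numeric(cs$effect_sizes), m = m)
      label <- sprintf("nu=%g", cs$nu)
    } else {
      stop("every case needs either 'eta' or 'nu' + 'effect_sizes'",
           call. = FALSE)
    }
    corr <- NULL
    if (!is.null(cs$rho)) {
      corr <- matrix(cs$rho, m, m); diag(corr) <- 1
    } else if (!is.null(cs$corr)) {
      corr <- do.call(rbind, cs$corr)
    }
    design <- trial_design(N = cs$N, m = m, alpha = alpha,
                           sigma = if (is.null(cs$sigma)) 1 else
                             as.numeric(cs$sigma),
                           corr = corr)
    list(design = design, policy = policy,
         label = sprintf("N=%d m=%d %s", design$N, design$m, label))
  })
  list(procedure = procedure, alpha = alpha,
       r = if (is.null(raw$r)) 100000L else as.integer(raw$r),
       seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
       rps = rps, cases = cases)
}

#' Run every case of a study configuration
#'
#' Calls [assess_allocation_bias()] for each case of a configuration read by
#' [read_study_config()] and binds the summaries into one data frame in the
#' layout of the package's reference tables.
#'
#' @param cfg A configuration list from [read_study_config()] (or a path to a
#'   YAML file, which is read first).
#' @param r,seed Optional overrides of the configured replicate count and
#'   seed.
#' @return A data frame with columns `procedure`, `case`, `N`, `m`, `rp`,
#'   `mean_rate`, `p_controlled`, `n_degenerate`, `r`, `seed`.
#' @export
run_study_config <- function(cfg, r = NULL, seed = NULL) {
  if (is.character(cfg)) cfg <- read_study_config(cfg)
  r <- if (is.null(r)) cfg$r else as.integer(r)
  seed <- if (is.null(seed)) cfg$seed else as.integer(seed)
  out <- lapply(cfg$cases, function(cs) {
    st <- assess_allocation_bias(cs$design, cs$policy, cfg$rps,
                                 procedure = cfg$procedure, r = r,
                                 seed = seed, keep_rates = FALSE)
    cbind(data.frame(procedure = cfg$procedure, case = cs$label,
                     N = cs$design$N, m = cs$design$m,
                     stringsAsFactors = FALSE),
          st$results, data.frame(seed = seed))
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
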