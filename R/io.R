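#' Write session logs to CSV with a JSON sidecar
#'
#' One row per trial (columns `participant`, `block`, `trial`,
#' `opponent_level` if present, `action_self`, `action_opp`,
#' `payoff_self`, `payoff_opp`; actions 0-indexed). A JSON sidecar
#' (`<path>.json`) stores the game spec, generating model, seeds and
#' generating parameters so the round trip is lossless.
#'
#' @param sessions Session data frame (e.g. from
#'   [simulate_experiment()]).
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  utils::write.csv(as.data.frame(sessions), path, row.names = FALSE)
  spec <- attr(sessions, "spec")
  side <- list(
    spec = if (is.null(spec)) NULL else unclass(spec),
    model = attr(sessions, "model"),
    seeds = attr(sessions, "seeds"),
    params = attr(sessions, "params"))
  jsonlite::write_json(side[!vapply(side, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read session logs written by [write_sessions()]
#'
#' Validates the schema (required columns, action range) and checks
#' every logged payoff against the game's payoff matrix; violations name
#' the offending row.
#'
#' @param path CSV path (sidecar `<path>.json` read if present).
#' @param spec Optional [game_spec()]; defaults to the sidecar's spec or
#'   the standard 3-action zero-sum game.
#' @return Session data frame with attributes restored from the sidecar.
#' @export
read_sessions <- function(path, spec = NULL) {
  d <- utils::read.csv(path)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path))
    jsonlite::read_json(side_path, simplifyVector = TRUE) else NULL
  if (is.null(spec)) {
    spec <- if (!is.null(side$spec))
      game_spec(side$spec$n_actions, side$spec$zero_sum,
                side$spec$loss_payoff, side$spec$label)
    else game_spec()
  }
  req <- c("participant", "block", "trial", "action_self", "action_opp",
           "payoff_self", "payoff_opp")
  missing <- setdiff(req, names(d))
  if (length(missing))
    stop("session file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  n <- spec$n_actions
  bad <- which(d$action_self < 0 | d$action_self >= n |
                 d$action_opp < 0 | d$action_opp >= n)
  if (length(bad))
    stop("action index out of range [0, ", n - 1, "] at row ", bad[1L])
  pi <- payoff_matrix(spec)
  exp_self <- pi[cbind(d$action_self + 1L, d$action_opp + 1L)]
  exp_opp <- pi[cbind(d$action_opp + 1L, d$action_self + 1L)]
  bad <- which(d$payoff_self != exp_self | d$payoff_opp != exp_opp)
  if (length(bad))
    stop("payoff inconsistent with the payoff matrix at row ", bad[1L],
         " (trial ", d$trial[bad[1L]], ")")
  structure(d, spec = spec, model = side$model, seeds = side$seeds,
            params = side$params)
}

#' Read a run configuration (YAML or JSON)
#'
#' Recognised blocks: `game` (`n_actions`, `zero_sum`, `loss_payoff`),
#' `opponents` (`alpha`, `beta`, `lapse`), `simulate` (`n_participants`,
#' `model`, `n_trials`, `levels`, `reps`), `fit` (`models`, `k_max`),
#' `seed`.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return Named list of settings with defaults filled in.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  defaults <- list(
    game = list(n_actions = 3L, zero_sum = TRUE, loss_payoff = 0),
    opponents = list(alpha = 0.3, beta = 3, lapse = 0.25),
    simulate = list(n_participants = 10L, model = "chase",
                    n_trials = 40L, levels = 0:2, reps = 2L),
    fit = list(models = names(chase_models()), k_max = 3L),
    seed = 1L)
  out <- utils::modifyList(defaults, if (is.null(cfg)) list() else cfg)
  out$spec <- game_spec(out$game$n_actions, out$game$zero_sum,
                        out$game$loss_payoff)
  out
}

cli_usage <- function() {
  cat("usage: chaser <subcommand> [options]\n",
      "subcommands:\n",
      "  simulate       --config c.yaml --seed S --out sessions.csv\n",
      "  fit            --in sessions.csv [--model m] [--kmax K] --out fits.csv\n",
      "  compare        --in fits.csv --out bms.json\n",
      "  regressors     --in sessions.csv --fits fits.csv --out regs.csv\n",
      "  recover-params [--n N] --seed S --out recovery.csv\n",
      "  recover-models [--n N] --seed S --out confusion.csv\n",
      "  ppc            --in sessions.csv --out ppc.csv\n",
      "  bu-curve       --in regs.csv --out curve.csv\n", sep = "")
}

cli_args <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("unexpected argument: ", args[i])
    key <- sub("^--", "", args[i])
    if (i == length(args)) stop("missing value for --", key)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

cli_log <- function(level, module, msg)
  message(sprintf("[%s] %s: %s", level, module, msg))

#' Command-line entry point
#'
#' Thin dispatcher over the package's functions; the installed script
#' `system.file("cli", "chaser.R", package = "chaser")` forwards
#' `commandArgs()` here. Deterministic given config and seed; returns a
#' non-zero exit code on any error.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code (0 on success), invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1L] %in% c("-h", "--help", "help")) {
    cli_usage(); return(invisible(0L))
  }
  sub <- args[1L]
  code <- tryCatch({
    opts <- cli_args(args[-1L])
    seed <- as.integer(opts$seed %||% 1L)
    switch(
      sub,
      simulate = {
        cfg <- if (is.null(opts$config)) read_config_defaults()
          else read_config(opts$config)
        sims <- simulate_experiment(
          cfg$simulate$n_participants, cfg$simulate$model,
          spec = cfg$spec, opponents = cfg$opponents,
          n_trials = cfg$simulate$n_trials, levels = cfg$simulate$levels,
          reps = cfg$simulate$reps, seed = seed)
        write_sessions(sims, opts$out %||% "sessions.csv")
        cli_log("INFO", "simulate", paste(nrow(sims), "trials written"))
      },
      fit = {
        sims <- read_sessions(opts$`in`)
        models <- if (is.null(opts$model)) names(chase_models())
          else strsplit(opts$model, ",")[[1L]]
        fits <- fit_dataset(sims, models, attr(sims, "spec"),
                            k_max = as.integer(opts$kmax %||% 3L))
        utils::write.csv(fits, opts$out %||% "fits.csv",
                         row.names = FALSE)
        cli_log("INFO", "fit", paste(nrow(fits), "fits written"))
      },
      compare = {
        fits <- utils::read.csv(opts$`in`)
        bms <- vb_bms(evidence_matrix(fits), seed = seed)
        jsonlite::write_json(
          list(alpha = bms$alpha, expected_freq = bms$expected_freq,
               ep = bms$ep, pxp = bms$pxp, bor = bms$bor,
               iterations = bms$iterations),
          opts$out %||% "bms.json", auto_unbox = TRUE, digits = NA)
        cli_log("INFO", "compare", sprintf("BOR = %.4f", bms$bor))
      },
      regressors = {
        sims <- read_sessions(opts$`in`)
        fits <- utils::read.csv(opts$fits)
        spec <- attr(sims, "spec")
        regs <- do.call(rbind, lapply(unique(sims$participant),
          function(p) {
            fr <- fits[fits$participant == p & fits$model == "chase", ]
            est <- list(alpha = fr$par_alpha, beta = fr$par_beta,
                        gamma = fr$par_gamma, lambda = fr$par_lambda,
                        kappa = fr$par_kappa)
            chase_regressors(sims[sims$participant == p, ], est, spec)
          }))
        utils::write.csv(regs, opts$out %||% "regressors.csv",
                         row.names = FALSE)
        cli_log("INFO", "regressors", paste(nrow(regs), "rows written"))
      },
      `recover-params` = {
        rep_ <- parameter_recovery(as.integer(opts$n %||% 48L),
                                   seed = seed)
        utils::write.csv(
          data.frame(parameter = names(rep_$correlations),
                     r = unname(rep_$correlations)),
          opts$out %||% "recovery.csv", row.names = FALSE)
        cli_log("INFO", "recover-params",
                sprintf("min r = %.3f", min(rep_$correlations)))
      },
      `recover-models` = {
        cm <- model_recovery(as.integer(opts$n %||% 20L), seed = seed)
        utils::write.csv(as.data.frame(cm$matrix),
                         opts$out %||% "confusion.csv")
        cli_log("INFO", "recover-models", "confusion matrix written")
      },
      ppc = {
        sims <- read_sessions(opts$`in`)
        ppc <- posterior_predictive_check(sims, attr(sims, "spec"))
        utils::write.csv(ppc, opts$out %||% "ppc.csv", row.names = FALSE)
        cli_log("INFO", "ppc", "curves written")
      },
      `bu-curve` = {
        regs <- utils::read.csv(opts$`in`)
        tc <- bu_timecourse(regs)
        utils::write.csv(tc$curve, opts$out %||% "bu_curve.csv",
                         row.names = FALSE)
        cli_log("INFO", "bu-curve",
                sprintf("mean slope = %.4f", mean(tc$slopes)))
      },
      { cli_usage(); stop("unknown subcommand: ", sub) })
    0L
  }, error = function(e) {
    cli_log("ERROR", sub, conditionMessage(e))
    1L
  })
  invisible(code)
}

read_config_defaults <- function() {
  tmp <- tempfile(fileext = ".yaml")
  writeLines("{}", tmp)
  on.exit(unlink(tmp))
  read_config(tmp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
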