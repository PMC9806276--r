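# Run configuration (YAML) and command dispatch. One nested config
# drives every module; unknown keys are rejected by name, every block
# is validated by constructing the corresponding module object before
# any run, and every run logs the seed and a config digest so results
# can be reproduced exactly.

#' Default run configuration
#'
#' One place defining every tunable of the toolkit. Blocks: `camera`,
#' `grille`, `protocol`, `detector`, `simulator`, plus the global
#' `seed` and `log_level`.
#'
#' @return a nested named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    camera = list(image_width_px = 1920, image_height_px = 1080,
                  boom_width_m = 3.3, n_cameras = 2, mount_height_m = 1),
    grille = list(n_cells = 11, row_height_px = 60, row_top_px = NULL,
                  area_threshold_px2 = 0),
    protocol = list(max_freq_hz = 10, min_open_s = 0.1),
    detector = list(input_size = 640, n_classes = 1, width_mult = 1,
                    neck_channels = 64, se_reduction = 4,
                    conf_thr = 0.5, nms_thr = 0.5,
                    lambda = c(0.5, 0.05, 1.0)),
    simulator = list(speed_kmh = 2, fps = 26.73, p_detect_frame = 0.85,
                     detect_speed_penalty = 0.06, sigma_loc_mm = 3,
                     sigma_vib0_mm = 5, latency_ms = 0,
                     nozzle_spacing_m = 0.15, density_per_m2 = 1,
                     area = c(20, 3)),
    seed = 0,
    log_level = "info"), class = "run_config")
}

overlay_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) {
      stop_config(sprintf("unknown configuration key `%s`", full))
    }
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(override[[key]])) {
        stop_config(sprintf("configuration key `%s` must be a block", full))
      }
      base[[key]] <- overlay_config(base[[key]], override[[key]], full)
    } else {
      base[key] <- override[key]  # keeps explicit NULLs
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, overlays it on [default_config()], rejects any
#' key that the defaults do not define (naming the offending key), and
#' validates every block by constructing the corresponding module
#' objects.
#'
#' @param path YAML file path, or NULL/missing file for pure defaults.
#' @return a validated `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop_config(sprintf("configuration file not found: %s", path))
    }
    user <- yaml::read_yaml(path)
    if (length(user)) cfg <- overlay_config(unclass(cfg), user)
    class(cfg) <- "run_config"
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  setup <- do.call(camera_setup, cfg$camera)
  gr <- cfg$grille
  gargs <- list(n_cells = gr$n_cells,
                image_width_px = cfg$camera$image_width_px,
                image_height_px = cfg$camera$image_height_px,
                row_height_px = gr$row_height_px,
                area_threshold_px2 = gr$area_threshold_px2)
  if (!is.null(gr$row_top_px)) gargs$row_top_px <- gr$row_top_px
  do.call(grille_config, gargs)
  check_positive(cfg$protocol$max_freq_hz, "protocol.max_freq_hz")
  if (cfg$protocol$min_open_s < 0) {
    stop_config("`protocol.min_open_s` must be non-negative")
  }
  dt <- cfg$detector
  detector_config(input_size = dt$input_size, n_classes = dt$n_classes,
                  width_mult = dt$width_mult,
                  neck_channels = dt$neck_channels,
                  se_reduction = dt$se_reduction, conf_thr = dt$conf_thr,
                  nms_thr = dt$nms_thr, lambda = dt$lambda)
  sm <- cfg$simulator
  do.call(sim_params, list(speed_kmh = sm$speed_kmh, fps = sm$fps,
                           p_detect_frame = sm$p_detect_frame,
                           detect_speed_penalty = sm$detect_speed_penalty,
                           sigma_loc_mm = sm$sigma_loc_mm,
                           sigma_vib0_mm = sm$sigma_vib0_mm,
                           latency_ms = sm$latency_ms,
                           nozzle_spacing_m = sm$nozzle_spacing_m))
  invisible(setup)
}

#' Write a configuration back to YAML
#' @param cfg a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# small stable digest of the configuration (31-bit polynomial hash of
# its deparse; for run logs, not cryptographic)
config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647
  sprintf("%08x", h)
}

log_msg <- function(cfg, level, fmt, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[cfg$log_level]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
}

cli_arg <- function(args, name, default = NULL) {
  i <- which(args == paste0("--", name))
  if (length(i) && i[1] < length(args)) args[i[1] + 1] else default
}

#' Dispatch a toolkit command
#'
#' The entry point behind the `spotspray` command line. Commands:
#' `calibrate`, `decide`, `encode`, `decode`, `rates`, `simulate`,
#' `gen-data`, `train`, `evaluate`, `predict`.
#'
#' @param command command name.
#' @param config a `run_config` (see [load_config()]).
#' @param args remaining command-line arguments (`--key value` pairs).
#' @return exit status (0 on success), invisibly.
#' @export
dispatch <- function(command, config = default_config(),
                     args = character()) {
  ok_commands <- c("calibrate", "decide", "encode", "decode", "rates",
                   "simulate", "gen-data", "train", "evaluate", "predict")
  if (!command %in% ok_commands) {
    message("usage: spotspray <", paste(ok_commands, collapse = "|"),
            "> [--config file.yaml] [options]")
    return(invisible(1L))
  }
  log_msg(config, "info", "command %s (seed %d, config %s)",
          command, config$seed, config_hash(config))
  status <- switch(command,
    calibrate = cmd_calibrate(config),
    decide = cmd_decide(config, args),
    encode = cmd_encode(args),
    decode = cmd_decode(args),
    rates = cmd_rates(args),
    simulate = cmd_simulate(config, args),
    `gen-data` = cmd_gen_data(config, args),
    train = cmd_train(config, args),
    evaluate = cmd_evaluate(config, args),
    predict = cmd_predict(config, args))
  invisible(status)
}

cmd_calibrate <- function(cfg) {
  setup <- do.call(camera_setup, cfg$camera)
  gs <- ground_scale(setup)
  cat(sprintf("ground scale: %.3f mm/px (unrounded %.6f)\n",
              gs$mm_per_px_rounded, gs$mm_per_px))
  # constraint figures are conventionally quoted at the rounded scale
  # (60 px x 0.859 mm/px = 51.54 mm)
  gs_r <- ground_scale(gs$mm_per_px_rounded)
  for (v in c(2, 3, 4)) {
    cc <- check_grille_constraint(cfg$grille$row_height_px, gs_r,
                                  motion_profile(v, cfg$simulator$fps))
    cat(sprintf(
      "  %d km/h: grille %.2f mm vs advance %.2f mm -> %s (margin %.2f mm)\n",
      v, cc$grille_mm, cc$advance_mm, if (cc$pass) "pass" else "FAIL",
      cc$margin_mm))
  }
  0L
}

cmd_decide <- function(cfg, args) {
  path <- cli_arg(args, "boxes")
  if (is.null(path)) { message("decide: need --boxes <csv>"); return(1L) }
  df <- utils::read.csv(path)
  gr <- load_config_grille(cfg)
  emit <- !is.null(cli_arg(args, "frames", NULL)) ||
    "--frames" %in% args
  for (f in sort(unique(df$frame))) {
    d <- df[df$frame == f, , drop = FALSE]
    b <- pred_boxes(d$x1, d$y1, d$x2, d$y2)
    bits <- decide_frame(b, gr)
    line <- paste0(unclass(bits), collapse = "")
    if (emit) {
      line <- paste(line,
                    paste(sprintf("%02x", as.integer(encode_valve_frame(bits))),
                          collapse = ""))
    }
    cat(line, "\n")
  }
  0L
}

load_config_grille <- function(cfg) {
  gargs <- list(n_cells = cfg$grille$n_cells,
                image_width_px = cfg$camera$image_width_px,
                image_height_px = cfg$camera$image_height_px,
                row_height_px = cfg$grille$row_height_px,
                area_threshold_px2 = cfg$grille$area_threshold_px2)
  if (!is.null(cfg$grille$row_top_px)) gargs$row_top_px <- cfg$grille$row_top_px
  do.call(grille_config, gargs)
}

cmd_encode <- function(args) {
  bits_s <- cli_arg(args, "bits")
  if (is.null(bits_s)) { message("encode: need --bits <01-string>"); return(1L) }
  bits <- as.integer(strsplit(bits_s, "")[[1]])
  cat(paste(sprintf("%02x", as.integer(encode_valve_frame(bits))),
            collapse = " "), "\n")
  0L
}

cmd_decode <- function(args) {
  hex_s <- cli_arg(args, "hex")
  if (is.null(hex_s)) { message("decode: need --hex <bytes>"); return(1L) }
  bytes <- as.raw(strtoi(strsplit(gsub("\\s", "", hex_s), "(?<=..)",
                                  perl = TRUE)[[1]], 16L))
  res <- tryCatch(decode_valve_frame(bytes), spotspray_frame_error = function(e) e)
  if (inherits(res, "condition")) {
    message("decode error [", res$code, "]: ", conditionMessage(res))
    return(1L)
  }
  cat(paste0(unclass(res), collapse = ""), "\n")
  0L
}

cmd_rates <- function(args) {
  path <- cli_arg(args, "counts")
  if (is.null(path)) { message("rates: need --counts <csv>"); return(1L) }
  df <- utils::read.csv(path)
  counts <- lapply(seq_len(nrow(df)), function(i) {
    trial_counts(df$n_total[i], df$n_identified[i], df$n_hit[i])
  })
  names(counts) <- if ("speed_kmh" %in% names(df)) df$speed_kmh else
    seq_len(nrow(df))
  tab <- trial_table(counts)
  utils::write.csv(tab, row.names = FALSE)
  0L
}

cmd_simulate <- function(cfg, args) {
  sm <- cfg$simulator
  speeds <- as.numeric(strsplit(cli_arg(args, "speeds", "2,3,4"), ",")[[1]])
  n_seeds <- as.integer(cli_arg(args, "seeds", "1"))
  scene <- generate_scene(sm$density_per_m2, sm$area, seed = cfg$seed)
  params <- sim_params(speed_kmh = speeds[1], fps = sm$fps,
                       p_detect_frame = sm$p_detect_frame,
                       detect_speed_penalty = sm$detect_speed_penalty,
                       sigma_loc_mm = sm$sigma_loc_mm,
                       sigma_vib0_mm = sm$sigma_vib0_mm,
                       latency_ms = sm$latency_ms,
                       nozzle_spacing_m = sm$nozzle_spacing_m,
                       seed = cfg$seed)
  setup <- do.call(camera_setup, cfg$camera)
  sweep <- speed_sweep(scene, speeds, params, n_seeds = n_seeds,
                       setup = setup)
  out <- cli_arg(args, "out")
  if (is.null(out)) utils::write.csv(sweep, row.names = FALSE)
  else utils::write.csv(sweep, out, row.names = FALSE)
  elog <- cli_arg(args, "events")
  if (!is.null(elog)) {
    r <- simulate_pass(scene, params, setup = setup)
    utils::write.csv(r$events, elog, row.names = FALSE)
  }
  0L
}

cmd_gen_data <- function(cfg, args) {
  dir <- cli_arg(args, "out", "synthetic_data")
  n <- as.integer(cli_arg(args, "n", "16"))
  size <- as.integer(cli_arg(args, "size", "320"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen_detection_data(n, size = size, seed = cfg$seed, dir = dir)
  log_msg(cfg, "info", "wrote %d PNG + VOC pairs to %s", n, dir)
  0L
}

load_voc_dir <- function(dir) {
  xmls <- list.files(dir, pattern = "\\.xml$", full.names = TRUE)
  lapply(xmls, function(p) {
    ann <- read_voc_xml(p)
    list(image = read_image(file.path(dir, ann$filename)),
         boxes = ann$boxes)
  })
}

cmd_train <- function(cfg, args) {
  dir <- cli_arg(args, "data")
  if (is.null(dir)) { message("train: need --data <voc dir>"); return(1L) }
  epochs <- as.integer(cli_arg(args, "epochs", "50"))
  samples <- load_voc_dir(dir)
  dt <- cfg$detector
  size <- dim(samples[[1]]$image)[1]
  dcfg <- detector_config(input_size = size, n_classes = dt$n_classes,
                          width_mult = dt$width_mult,
                          neck_channels = dt$neck_channels,
                          se_reduction = dt$se_reduction,
                          conf_thr = dt$conf_thr, nms_thr = dt$nms_thr,
                          lambda = dt$lambda)
  model <- build_detector(dcfg, seed = cfg$seed)
  tr <- train_detector(model, samples, epochs = epochs, seed = cfg$seed)
  out <- cli_arg(args, "out", "detector_weights.rds")
  save_detector(tr$model, out, history = tr$history)
  log_msg(cfg, "info", "loss %.4f -> %.4f; checkpoint epoch %d -> %s",
          tr$history$loss[1], tr$history$loss[nrow(tr$history)],
          tr$best_epoch, out)
  0L
}

cmd_evaluate <- function(cfg, args) {
  dir <- cli_arg(args, "data")
  wpath <- cli_arg(args, "weights")
  if (is.null(dir) || is.null(wpath)) {
    message("evaluate: need --data <voc dir> --weights <rds>")
    return(1L)
  }
  model <- load_detector(wpath)
  samples <- load_voc_dir(dir)
  det_all <- no_boxes(); gt_all <- no_boxes()
  off <- 0
  for (s in samples) {
    d <- detect_weeds(model, s$image)
    g <- s$boxes
    d$x1 <- d$x1 + off; d$x2 <- d$x2 + off
    g$x1 <- g$x1 + off; g$x2 <- g$x2 + off
    det_all <- rbind(det_all, d); gt_all <- rbind(gt_all, g)
    off <- off + dim(s$image)[2] + 64  # separate images in eval space
  }
  class(det_all) <- class(gt_all) <- c("pred_box", "data.frame")
  print(evaluate_detections(det_all, gt_all))
  0L
}

cmd_predict <- function(cfg, args) {
  ipath <- cli_arg(args, "image")
  wpath <- cli_arg(args, "weights")
  if (is.null(ipath) || is.null(wpath)) {
    message("predict: need --image <png> --weights <rds>")
    return(1L)
  }
  model <- load_detector(wpath)
  det <- detect_weeds(model, read_image(ipath))
  utils::write.csv(det, row.names = FALSE)
  0L
}

#' Save / load detector weights
#'
#' The checkpoint stores the configuration, the initialisation seed,
#' every parameter value and batch-normalisation running statistic, and
#' an optional training history.
#'
#' @param model a [build_detector()] object.
#' @param path RDS file path.
#' @param history optional training history to embed.
#' @return `path` (save) / a `weed_detector` (load).
#' @export
save_detector <- function(model, path, history = NULL) {
  params <- detector_params(model)
  bnl <- do.call(c, lapply(detector_layers(model), collect_bn_layers))
  saveRDS(list(config = model$config, seed = model$seed,
               values = snapshot_params(params),
               bn = lapply(bnl, function(l) list(mu = l$run_mu,
                                                 var = l$run_var)),
               history = history),
          path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  st <- readRDS(path)
  model <- build_detector(st$config, seed = st$seed)
  params <- detector_params(model)
  restore_params(params, st$values)
  bnl <- do.call(c, lapply(detector_layers(model), collect_bn_layers))
  for (i in seq_along(bnl)) {
    bnl[[i]]$run_mu <- st$bn[[i]]$mu
    bnl[[i]]$run_var <- st$bn[[i]]$var
  }
  attr(model, "history") <- st$history
  model
}
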