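## Session-level cache for expensive fixtures so several test files can
## share one mini build / run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache, inherits = FALSE)
}

get_mini_sys <- function() cached("mini_sys", make_mini_system(seed = 1))
get_mini_run <- function() cached("mini_run", run_protocol(get_mini_sys()))
get_mini_report <- function() cached("mini_report", analyze_run(get_mini_run()))

## a small calibration block shared by tensile tests
get_calib_block <- function()
  cached("calib_block",
         build_bead_block(L = c(60, 30, 30), spacing = 5, k = 0.28,
                          k_b = 2.1, seed = 7))

## synthetic run record for analysis tests: n_spat spatulae with
## hand-specified per-spatula force and contact series
fake_run <- function(f_sub_mat, contacts_mat, dt_ls_ns = 1.4,
                     phase = NULL, orientation = NULL) {
  n_steps <- nrow(f_sub_mat); n_spat <- ncol(f_sub_mat)
  if (is.null(phase)) phase <- rep("pulloff", n_steps)
  if (is.null(orientation))
    orientation <- ifelse(seq_len(n_spat) %% 2 == 1, "tip_first",
                          "pad_parallel")
  steps <- seq_len(n_steps)
  spat <- dplyr::bind_rows(lapply(seq_len(n_spat), function(s)
    tibble::tibble(step = steps, phase = phase, time_ns = steps * dt_ls_ns,
                   spatula = s, orientation = orientation[s],
                   f_sub = f_sub_mat[, s], f_sub_x = 0,
                   contacts = contacts_mat[, s],
                   tip_x = 0, tip_y = 0, pad_x = 0, pad_y = 0)))
  seta <- tibble::tibble(step = steps, phase = phase,
                         time_ns = steps * dt_ls_ns,
                         f_sub_x = 0, f_sub = rowSums(f_sub_mat),
                         f_ap = rowSums(f_sub_mat),
                         f_driver = rowSums(f_sub_mat),
                         contacts = rowSums(contacts_mat))
  structure(list(seta = seta, spatula = spat, dt_ls_ns = dt_ls_ns,
                 n_spat = n_spat,
                 phase_end = c(preload = 0L, relax = 0L)),
            class = "seta_run")
}
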