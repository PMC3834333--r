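# Shared fixtures: small, fast synthetic objects built in code.

tiny_protocol <- function(n_pulses = 1, frequency = 1, pre = 2, post = 2.5) {
  stimulus_protocol(n_pulses, frequency, pre_window = pre, post_window = post)
}

tiny_geometry <- function(seed = 3, dims = c(64, 64)) {
  make_geometry(area_range = c(160, 260), dims = dims,
                dendrite_length_px = c(18, 22), seed = seed)
}

clean_noise <- function(seed = 1) {
  noise_params(dark_offset = 100, read_noise_sd = 0, photon_scale = 1,
               shot_noise = FALSE, seed = seed)
}

# dark-subtract + F0 + dff in one go
stack_to_dff <- function(stack, protocol) {
  sub <- subtract_dark(stack)
  compute_dff(sub, compute_f0(sub, protocol))
}

# hand-built image_stack from an array (frames x rows x cols)
manual_stack <- function(data, dark = NULL, dt = 0.01, px = 1.18) {
  d <- dim(data)
  if (is.null(dark)) dark <- array(0, c(1, d[2], d[3]))
  structure(list(data = data, dark_frames = dark, frame_interval = dt,
                 pixel_size = px, time = (seq_len(d[1]) - 1) * dt),
            class = "image_stack")
}

# hand-built dff_stack from an array
manual_dff <- function(dff, f0 = NULL, dt = 0.01, px = 1.18) {
  d <- dim(dff)
  if (is.null(f0)) f0 <- matrix(1, d[2], d[3])
  structure(list(dff = dff, f0 = f0, valid = f0 > 0,
                 time = (seq_len(d[1]) - 1) * dt,
                 frame_interval = dt, pixel_size = px),
            class = "dff_stack")
}

# straight horizontal test dendrite with full control over length/width
manual_geom <- function(n_beyond = 20, width_um = 3.2, row = 30,
                        border_col = 20, branch_at = integer(0),
                        pixel_size = 1.18) {
  n <- border_col + n_beyond - 1
  path <- cbind(row = rep(row, n), col = seq_len(n))
  list(soma_center = c(row, 10), soma_radius_px = border_col - 10.5,
       nucleus_radius_px = 3,
       dendrites = list(list(path = path,
                             width_um = rep(width_um, n),
                             border = border_col,
                             branch_at = branch_at)),
       pixel_size = pixel_size, dims = c(64, 64))
}
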