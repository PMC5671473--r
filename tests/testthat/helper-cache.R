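# The default anatomical phantom and its configuration-8 run are used by
# several test files; build them once per session.
.tp_cache <- new.env(parent = emptyenv())

tp_cached <- function(key, expr) {
  if (!exists(key, envir = .tp_cache))
    assign(key, expr, envir = .tp_cache)
  get(key, envir = .tp_cache)
}

default_phantom <- function() tp_cached("ph", generate_phantom(phantom_spec()))

default_run8 <- function() tp_cached("run8", {
  ph <- default_phantom()
  run_subject(ph$aparc, ph$suit, ph$c1, ph$c2, ph$c3, ph$c4, ph$c5, ph$pet,
              psf_fwhm_mm = 6, config = roi_config(8L))
})

# A small volume constructor for hand-built fixtures.
vol <- function(data, type = "scalar", vs = c(1, 1, 1)) {
  switch(type,
         scalar = scalar_volume(data, vs),
         label = labeled_volume(data, vs),
         prob = probability_volume(data, vs))
}

# SUVR-like scalar volume with a recorded reference mean of 1 (hand-built
# fields are already in ratio units).
as_suvr <- function(data, vs = c(1, 1, 1)) {
  out <- scalar_volume(data, vs)
  attr(out, "reference_mean") <- 1
  out
}
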