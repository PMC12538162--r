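# Random protocol messages and a field-level view for round-trip checks.

random_message <- function() {
  kind <- sample(c("PARAMS", "TRIGGER", "MOCK", "PING", "CALIBRATE"), 1)
  payload <- switch(kind,
    PARAMS = lapply(sample(4, sample(3, 1)), function(i) {
      p <- random_params()
      p$laser_id <- i
      p
    }),
    MOCK = list(flag = sample(c(TRUE, FALSE), 1)),
    CALIBRATE = list(steps = round(sort(runif(5)), 3)),
    list())
  laser_msg(kind, payload)
}

msg_fields <- function(m) {
  if (m$kind == "PARAMS") {
    list(kind = m$kind, payload = lapply(m$payload, unclass))
  } else {
    list(kind = m$kind, payload = m$payload)
  }
}
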