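## Internal dispatch helpers shared by fitting, prediction and reporting.

## Signal at concentrations `conc` (mol/L) under any parameter object.
predictParams <- function(params, conc) {
  if (is(params, "GLParams")) return(glValue(log(conc), params))
  if (is(params, "FourPLParams")) return(fourPLValue(log(conc), params))
  if (is(params, "FivePLParams")) return(fivePLValue(conc, params))
  stop("unknown parameter class: ", class(params), call. = FALSE)
}

paramsToVector <- function(params) {
  if (is(params, "GLParams"))
    return(c(sFloor = params@sFloor, sSpan = params@sSpan,
             rate = params@rate, logInfl = params@logInfl, nu = params@nu))
  if (is(params, "FourPLParams"))
    return(c(sFloor = params@sFloor, sSpan = params@sSpan,
             rate = params@rate, logInfl = params@logInfl))
  if (is(params, "FivePLParams"))
    return(c(sFloor = params@sFloor, sSpan = params@sSpan,
             slopeB = params@slopeB, cMid = params@cMid,
             asymG = params@asymG))
  stop("unknown parameter class: ", class(params), call. = FALSE)
}

vectorToParams <- function(model, v) {
  switch(model,
    "GL" = GLParams(v[["sFloor"]], v[["sSpan"]], v[["rate"]],
                    v[["logInfl"]], v[["nu"]]),
    "4PL" = FourPLParams(v[["sFloor"]], v[["sSpan"]], v[["rate"]],
                         v[["logInfl"]]),
    "5PL" = FivePLParams(v[["sFloor"]], v[["sSpan"]], v[["slopeB"]],
                         v[["cMid"]], v[["asymG"]]),
    stop("unknown model: ", model, call. = FALSE))
}
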