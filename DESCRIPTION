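Package: sitpoly
Title: Sterile Insect Technique Models Under Female Multiple Mating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compartmental and agent-based models of the sterile insect
    technique (SIT) for pest populations with polyandrous females,
    calibrated for Drosophila suzukii. Provides the full and reduced
    ordinary differential equation models of larval and adult dynamics
    under constant sterilized-male releases, closed-form eradication
    thresholds and bifurcation analysis, a stochastic daily-step
    agent-based simulator with six sperm-use scenarios (first- and
    last-male precedence, mixed use, and preferences for fertile or
    sterile sperm), and replicate experiment tooling that summarizes
    control efficiency as percentage reductions in the area under the
    larval-density curve.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
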