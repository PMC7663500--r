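Package: dyndse
Title: Simulation-Based Design Space Exploration for Context-Adaptive
    Wearable Biosignal Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multi-objective design space exploration for wearable
    event-spotting devices. Enumerates hardware/software configurations
    (spotting algorithm, sampling strategy, microcontroller, runtime mode),
    simulates event-spotting pipelines on streamed surface-EMG data under
    uniform or context-adaptive duty-cycle sampling, and estimates retrieval
    performance, execution time, energy consumption, memory demand and
    communication latency from analytical machine-cycle cost models.
    Feasible and optimal configurations are reported against user-stated
    requirements. Includes a seeded synthetic EMG generator emulating
    day-long chewing-activity recordings so the full pipeline can be
    exercised without access to private sensor data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
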