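# Preset for fitting measured double-pendulum data (user supplies the file).
# Set `input` to a CSV with the pendulum observable, e.g. sin(theta2),
# sampled at 1 kHz.
# input = pendulum.csv
# column = x
dt = 0.001
m = 101
r = 5
variant = shavok
centred = true
closed = false
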