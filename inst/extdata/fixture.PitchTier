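File type = "ooTextFile"
Object class = "PitchTier"

xmin = 0
xmax = 2
points: size = 6
points [1]:
    number = 0.20
    value = 170
points [2]:
    number = 0.40
    value = 190
points [3]:
    number = 0.50
    value = 210
points [4]:
    number = 1.10
    value = 160
points [5]:
    number = 1.24
    value = 150
points [6]:
    number = 1.40
    value = 180
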