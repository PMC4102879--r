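File type = "ooTextFile"
Object class = "TextGrid"

xmin = 0
xmax = 2
tiers? <exists>
size = 2
item []:
    item [1]:
        class = "IntervalTier"
        name = "syllables"
        xmin = 0
        xmax = 2
        intervals: size = 6
        intervals [1]:
            xmin = 0
            xmax = 0.10
            text = ""
        intervals [2]:
            xmin = 0.10
            xmax = 0.30
            text = "S1"
        intervals [3]:
            xmin = 0.30
            xmax = 0.56
            text = "S2"
        intervals [4]:
            xmin = 0.56
            xmax = 1.00
            text = ""
        intervals [5]:
            xmin = 1.00
            xmax = 1.22
            text = "S1"
        intervals [6]:
            xmin = 1.22
            xmax = 1.44
            text = "S2"
    item [2]:
        class = "TextTier"
        name = "tones"
        xmin = 0
        xmax = 2
        points: size = 4
        points [1]:
            number = 0.32
            mark = "L"
        points [2]:
            number = 0.50
            mark = "H"
        points [3]:
            number = 1.24
            mark = "L"
        points [4]:
            number = 1.40
            mark = "H"
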