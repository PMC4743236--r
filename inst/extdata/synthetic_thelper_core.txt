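nodes 40
node G01 core
node G02 core
node G03 core
node G04 core
node G05 core
node G06 core
node G07 core
node G08 core
node G09 core
node G10 core
node G11 core
node G12 core
node G13 core
node G14 core
node G15 core
node G16 core
node G17 core
node G18 core
node G19 core
node G20 core
node G21 core
node G22 core
node G23 core
node G24 core
node G25 core
node G26 core
node G27 core
node G28 core
node G29 core
node G30 core
node G31 core
node G32 core
node G33 core
node G34 core
node G35 core
node G36 core
node G37 core
node G38 core
node G39 core
node G40 core
fn G01 G25 table 11
fn G02 - table 0
fn G03 G18,G31 table 0100
fn G04 - table 1
fn G05 G39,G40 table 0010
fn G06 G28 table 00
fn G07 G22,G25 table 1100
fn G08 G35,G36 table 0101
fn G09 G36 table 10
fn G10 G23,G29 table 0100
fn G11 G12 table 10
fn G12 G05,G02,G30 table 00000110
fn G13 - table 1
fn G14 G17,G28,G22 table 10111111
fn G15 G11,G19,G17,G16 table 1011101100000111
fn G16 G39 table 10
fn G17 G28,G14 table 0100
fn G18 G24 table 00
fn G19 G01,G37 table 0110
fn G20 G04,G39 table 0101
fn G21 G01,G16 table 1000
fn G22 - table 0
fn G23 G34 table 10
fn G24 - table 0
fn G25 G22,G08 table 1011
fn G26 G01 table 11
fn G27 - table 1
fn G28 G40 table 11
fn G29 - table 0
fn G30 G36 table 00
fn G31 G09,G22 table 1001
fn G32 - table 1
fn G33 G25 table 10
fn G34 G33 table 10
fn G35 G06 table 00
fn G36 G08,G38 table 0011
fn G37 G17 table 11
fn G38 G09 table 01
fn G39 - table 1
fn G40 G19,G11 table 0000
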