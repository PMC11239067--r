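abbrev,expansion
ST,STREET
AVE,AVENUE
AV,AVENUE
BLVD,BOULEVARD
RD,ROAD
DR,DRIVE
PL,PLACE
LN,LANE
CT,COURT
TER,TERRACE
PKWY,PARKWAY
PKY,PARKWAY
HWY,HIGHWAY
EXPY,EXPRESSWAY
SQ,SQUARE
CIR,CIRCLE
E,EAST
W,WEST
N,NORTH
S,SOUTH
NE,NORTHEAST
NW,NORTHWEST
SE,SOUTHEAST
SW,SOUTHWEST
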