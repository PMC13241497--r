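activity,intensity,code,met
resting,mild,07020,1.0
sleeping,mild,07030,0.95
sitting quietly,mild,07021,1.3
watching tv,mild,07020,1.3
watching television,mild,07020,1.3
reading,mild,09030,1.3
eating,mild,13030,1.5
eating,moderate,13035,2.0
desk work,mild,11580,1.5
cooking,mild,05049,2.0
cooking,moderate,05050,2.5
washing dishes,mild,05041,1.8
washing dishes,moderate,05043,2.5
housekeeping,mild,05010,2.3
housekeeping,moderate,05011,3.3
housekeeping,vigorous,05012,3.8
ironing,mild,05070,1.8
laundry,moderate,05090,2.0
vacuuming,moderate,05043,3.3
gardening,mild,08245,2.3
gardening,moderate,08246,3.8
gardening,vigorous,08247,5.0
tinkering,moderate,06235,3.0
crafts,mild,05181,1.8
shopping,mild,05060,2.3
shopping,moderate,05065,2.5
walking,mild,17151,2.0
walking,moderate,17170,3.5
walking,vigorous,17230,5.0
walking slow,mild,17152,2.0
walking brisk,moderate,17200,4.3
cycling,moderate,01011,6.8
cycling,vigorous,01013,8.0
stair climbing,vigorous,17133,8.0
sports,moderate,15000,4.5
sports,vigorous,15010,7.0
car driving,mild,16010,2.5
car passenger,mild,16015,1.3
train passenger,mild,16016,1.3
visiting friends,mild,09055,1.5
playing music,mild,10074,2.0
knitting,mild,09100,1.3
light conversation,mild,09040,1.3
telephone call,mild,09105,1.3
walking,any,17170,3.5
housekeeping,any,05011,3.3
gardening,any,08246,3.8
cycling,any,01011,6.8
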