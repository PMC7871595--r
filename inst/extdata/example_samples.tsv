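sample	population	region	lat	lon
NW1_01	NW1	NW	36.6122572495602	101.898469269741
NW1_02	NW1	NW	36.6122572495602	101.898469269741
NW1_03	NW1	NW	36.6122572495602	101.898469269741
NW1_04	NW1	NW	36.6122572495602	101.898469269741
NW1_05	NW1	NW	36.6122572495602	101.898469269741
NW1_06	NW1	NW	36.6122572495602	101.898469269741
NW1_07	NW1	NW	36.6122572495602	101.898469269741
NW1_08	NW1	NW	36.6122572495602	101.898469269741
CC1_01	CC1	CC	30.8604487545323	106.283097633068
CC1_02	CC1	CC	30.8604487545323	106.283097633068
CC1_03	CC1	CC	30.8604487545323	106.283097633068
CC1_04	CC1	CC	30.8604487545323	106.283097633068
CC1_05	CC1	CC	30.8604487545323	106.283097633068
CC1_06	CC1	CC	30.8604487545323	106.283097633068
CC1_07	CC1	CC	30.8604487545323	106.283097633068
CC1_08	CC1	CC	30.8604487545323	106.283097633068
CC1_09	CC1	CC	30.8604487545323	106.283097633068
CC1_10	CC1	CC	30.8604487545323	106.283097633068
CC2_01	CC2	CC	31.4281106192619	107.153478926374
CC2_02	CC2	CC	31.4281106192619	107.153478926374
CC2_03	CC2	CC	31.4281106192619	107.153478926374
CC2_04	CC2	CC	31.4281106192619	107.153478926374
CC2_05	CC2	CC	31.4281106192619	107.153478926374
CC2_06	CC2	CC	31.4281106192619	107.153478926374
CC2_07	CC2	CC	31.4281106192619	107.153478926374
CC2_08	CC2	CC	31.4281106192619	107.153478926374
CC2_09	CC2	CC	31.4281106192619	107.153478926374
CC2_10	CC2	CC	31.4281106192619	107.153478926374
CE1_01	CE1	CE	31.2555396355223	116.999782433501
CE1_02	CE1	CE	31.2555396355223	116.999782433501
CE1_03	CE1	CE	31.2555396355223	116.999782433501
CE1_04	CE1	CE	31.2555396355223	116.999782433501
CE1_05	CE1	CE	31.2555396355223	116.999782433501
CE1_06	CE1	CE	31.2555396355223	116.999782433501
CE1_07	CE1	CE	31.2555396355223	116.999782433501
CE1_08	CE1	CE	31.2555396355223	116.999782433501
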